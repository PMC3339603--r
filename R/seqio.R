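#' Build an EST record set
#'
#' An EST set is a plain `data.frame` with one row per sequence and columns
#' `id`, `library`, `seq`, `length`. Sequences are uppercased, `U` is mapped
#' to `T`, and any IUPAC ambiguity code other than N is mapped to N (dbEST
#' records routinely carry such codes and N breaks repeat runs downstream,
#' which is the conservative behaviour).
#'
#' @param id character vector of unique identifiers.
#' @param seq character vector of nucleotide sequences.
#' @param library single library label (e.g. "OYF") or vector.
#' @return data.frame with columns id, library, seq, length.
#' @export
est_set <- function(id, seq, library = "NA") {
  if (length(id) != length(seq)) stopf("id and seq lengths differ")
  if (!length(id)) stopf("no sequences")
  dup <- id[duplicated(id)]
  if (length(dup)) stopf("duplicate identifier: %s", dup[1])
  s <- toupper(chartr("Uu", "Tt", seq))
  n_ambig <- sum(nchar(s) - nchar(gsub("[^ACGTN]", "", s)))
  if (n_ambig > 0) {
    s <- gsub("[^ACGTN]", "N", s)
    message(sprintf("mapped %d ambiguity residues to N", n_ambig))
  }
  len <- nchar(s)
  if (any(len == 0)) stopf("empty sequence: %s", id[len == 0][1])
  data.frame(id = as.character(id), library = as.character(library),
             seq = s, length = len, stringsAsFactors = FALSE)
}

#' Read an EST library from FASTA
#'
#' @param path FASTA file (wrapped or unwrapped lines).
#' @param library library label attached to every record.
#' @return EST set data.frame (see [est_set()]).
#' @export
read_est_fasta <- function(path, library = "NA") {
  if (!file.exists(path)) stopf("file not found: %s", path)
  x <- tryCatch(Biostrings::readBStringSet(path),
                error = function(e) stopf("no sequences in %s", path))
  if (!length(x)) stopf("no sequences in %s", path)
  ids <- sub("\\s.*$", "", names(x))
  est_set(ids, as.character(x), library)
}

#' Write an EST set to FASTA
#'
#' @param ests EST set data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_est_fasta <- function(ests, path) {
  x <- Biostrings::BStringSet(stats::setNames(ests$seq, ests$id))
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' Clip terminal homopolymer tails and drop short ESTs
#'
#' cDNA reads carry 3' poly-A (and, for reverse-cloned inserts, 5' poly-T)
#' runs that are cloning artifacts of the mRNA tail, not transcript sequence.
#' `clean_est()` clips a terminal run when it reaches `max_terminal_polyA`
#' nucleotides and then rejects any record shorter than `min_len`. Rejection
#' is a reported state, not an error.
#'
#' @param ests EST set data.frame.
#' @param min_len minimum retained length after clipping (nt).
#' @param max_terminal_polyA minimum terminal homopolymer run that triggers
#'   clipping (nt).
#' @return list with `kept` (cleaned EST set) and `report` (data.frame with
#'   id, action, clipped_5p, clipped_3p, reason).
#' @export
clean_est <- function(ests, min_len = 100, max_terminal_polyA = 12) {
  s <- ests$seq
  a3 <- attr(regexpr("A+$", s), "match.length")
  a3[a3 < max_terminal_polyA] <- 0L
  s <- substr(s, 1L, nchar(s) - pmax(a3, 0L))
  t5 <- attr(regexpr("^T+", s), "match.length")
  t5[t5 < max_terminal_polyA] <- 0L
  s <- substr(s, pmax(t5, 0L) + 1L, nchar(s))
  len <- nchar(s)
  keep <- len >= min_len
  action <- ifelse(!keep, "reject",
                   ifelse(a3 > 0 | t5 > 0, "clip", "pass"))
  report <- data.frame(id = ests$id, action = action,
                       clipped_5p = pmax(t5, 0L), clipped_3p = pmax(a3, 0L),
                       reason = ifelse(keep, "", "too_short"),
                       stringsAsFactors = FALSE)
  kept <- ests[keep, , drop = FALSE]
  kept$seq <- s[keep]
  kept$length <- len[keep]
  rownames(kept) <- NULL
  list(kept = kept, report = report)
}

#' Write a cleanup report as TSV
#'
#' @param report the `report` element returned by [clean_est()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cleanup_report <- function(report, path) write_tsv(report, path)

#' Read a mature miRNA reference set from FASTA
#'
#' Accepts RNA or DNA alphabet; sequences are kept as RNA internally.
#' Records outside the 18-26 nt sanity band for mature miRNAs are dropped
#' with a message.
#'
#' @param path FASTA file of mature miRNA sequences.
#' @return data.frame with columns id, seq (RNA), length.
#' @export
read_mirna_fasta <- function(path) {
  x <- tryCatch(Biostrings::readBStringSet(path),
                error = function(e) stopf("no sequences in %s", path))
  if (!length(x)) stopf("no sequences in %s", path)
  ids <- sub("\\s.*$", "", names(x))
  dup <- ids[duplicated(ids)]
  if (length(dup)) stopf("duplicate identifier: %s", dup[1])
  s <- dna_to_rna(toupper(as.character(x)))
  len <- nchar(s)
  ok <- len >= 18 & len <= 26
  if (any(!ok)) message(sprintf("dropped %d records outside 18-26 nt", sum(!ok)))
  data.frame(id = ids[ok], seq = s[ok], length = len[ok],
             stringsAsFactors = FALSE)
}
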