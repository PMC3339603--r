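# read x consensus-position character matrix for one contig; NA outside the
# read span, "-" where the read carries a deletion
placement_matrix <- function(contig) {
  pl <- contig$placements
  width <- nchar(contig$consensus)
  mat <- matrix(NA_character_, nrow(pl), width,
                dimnames = list(pl$read_id, NULL))
  for (m in seq_len(nrow(pl))) {
    ch <- seq_chars(pl$aligned_seq[m])
    mat[m, (pl$offset[m] + 1):(pl$offset[m] + length(ch))] <- ch
  }
  mat
}

#' Redundancy-based SNP and indel calling on one contig
#'
#' Scans every alignment column of the contig. A column is called when its
#' depth reaches `min_depth` and at least two distinct alleles each occur in
#' at least `min_allele` reads -- the redundancy requirement that separates
#' real polymorphism from singleton sequencing errors. Columns with more
#' than two qualifying alleles report the top two by count (alphabetical
#' tie-break, the gap symbol sorting first). A gap allele makes the call an
#' indel; substitutions are classified as transition ({A,G} or {C,T}) or
#' transversion. Runs of adjacent indel columns are collapsed to one event
#' at the leftmost position, so multi-residue gaps count once.
#'
#' @param contig list with `consensus` and `placements` (see
#'   [cluster_set()]).
#' @param contig_id identifier carried into the calls.
#' @param min_depth minimum column depth.
#' @param min_allele minimum reads per allele.
#' @return data.frame with contig_id, pos (0-based), allele1, allele2,
#'   count1, count2, depth, kind, subst_class, redundancy.
#' @export
call_snps <- function(contig, contig_id = "contig", min_depth = 4,
                      min_allele = 2) {
  mat <- placement_matrix(contig)
  allele_set <- c("-", "A", "C", "G", "T")
  counts <- vapply(allele_set, function(a)
    as.integer(colSums(mat == a, na.rm = TRUE)), integer(ncol(mat)))
  if (ncol(mat) == 1) counts <- matrix(counts, nrow = 1,
                                       dimnames = list(NULL, allele_set))
  depth_all <- rowSums(counts)
  cand <- which(depth_all >= min_depth &
                  rowSums(counts >= min_allele) >= 2)
  rows <- list()
  for (p in cand) {
    tab <- counts[p, ]
    qual <- tab[tab >= min_allele]
    depth <- depth_all[p]
    ord <- order(-qual, names(qual))   # count desc, then "-" < A < C < G < T
    top <- qual[ord[1:2]]
    alleles <- names(top)
    is_indel <- "-" %in% alleles
    subst_class <- if (is_indel) "none"
    else if (all(alleles %in% c("A", "G")) ||
             all(alleles %in% c("C", "T"))) "transition" else "transversion"
    rows[[length(rows) + 1]] <- data.frame(
      contig_id = contig_id, pos = p - 1L,
      allele1 = alleles[1], allele2 = alleles[2],
      count1 = as.integer(top[1]), count2 = as.integer(top[2]),
      depth = depth,
      kind = if (is_indel) "indel" else "substitution",
      subst_class = subst_class,
      redundancy = as.integer(min(top)), stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty_snp_df())
  calls <- do.call(rbind, rows)
  collapse_adjacent_indels(calls)
}

empty_snp_df <- function() {
  data.frame(contig_id = character(0), pos = integer(0),
             allele1 = character(0), allele2 = character(0),
             count1 = integer(0), count2 = integer(0), depth = integer(0),
             kind = character(0), subst_class = character(0),
             redundancy = integer(0), stringsAsFactors = FALSE)
}

# one indel event per maximal run of adjacent indel columns
collapse_adjacent_indels <- function(calls) {
  if (nrow(calls) < 2) return(calls)
  calls <- calls[order(calls$pos), , drop = FALSE]
  keep <- rep(TRUE, nrow(calls))
  i <- 1
  while (i <= nrow(calls)) {
    if (calls$kind[i] == "indel") {
      j <- i
      while (j + 1 <= nrow(calls) && calls$kind[j + 1] == "indel" &&
             calls$pos[j + 1] == calls$pos[j] + 1) j <- j + 1
      if (j > i) keep[(i + 1):j] <- FALSE
      i <- j + 1
    } else i <- i + 1
  }
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# allele labels (1/2/NA) per read for one call
call_allele_vector <- function(call, mat) {
  col <- mat[, call$pos + 1L]
  out <- rep(NA_integer_, length(col))
  out[!is.na(col) & col == call$allele1] <- 1L
  out[!is.na(col) & col == call$allele2] <- 2L
  out
}

#' Co-segregation score of a SNP call
#'
#' Measures whether the call contributes to a haplotype definition: among
#' the other SNP columns of the same contig, the fraction whose bipartition
#' of the commonly covering reads matches this call's bipartition. Sibling
#' columns enter the denominator only when each side of their bipartition
#' keeps at least two of the common reads; a contig's lone SNP scores 0.
#'
#' @param calls data.frame of calls on one contig (from [call_snps()]).
#' @param contig the contig (consensus + placements).
#' @return numeric vector of scores in `[0, 1]`, one per call.
#' @export
coseg_scores <- function(calls, contig) {
  n <- nrow(calls)
  if (!n) return(numeric(0))
  mat <- placement_matrix(contig)
  av <- lapply(seq_len(n), function(i) call_allele_vector(calls[i, ], mat))
  scores <- numeric(n)
  for (i in seq_len(n)) {
    num <- 0L; den <- 0L
    for (j in seq_len(n)) {
      if (i == j) next
      common <- which(!is.na(av[[i]]) & !is.na(av[[j]]))
      if (length(common) < 4) next
      sides_j <- table(av[[j]][common])
      if (length(sides_j) < 2 || min(sides_j) < 2) next
      den <- den + 1L
      tab <- table(av[[i]][common], av[[j]][common])
      perfect <- all(rowSums(tab > 0) <= 1) && all(colSums(tab > 0) <= 1)
      if (perfect && nrow(tab) == 2) num <- num + 1L
    }
    scores[i] <- if (den > 0) num / den else 0
  }
  scores
}

#' Call SNPs across all contigs of a cluster set
#'
#' @param cs a `cluster_set`.
#' @inheritParams call_snps
#' @return data.frame of calls with a `coseg` column appended.
#' @export
call_snps_cluster_set <- function(cs, min_depth = 4, min_allele = 2) {
  out <- lapply(names(cs$contigs), function(cid) {
    calls <- call_snps(cs$contigs[[cid]], cid, min_depth, min_allele)
    if (nrow(calls)) calls$coseg <- coseg_scores(calls, cs$contigs[[cid]])
    calls
  })
  res <- do.call(rbind, out)
  if (is.null(res) || !nrow(res)) {
    res <- empty_snp_df(); res$coseg <- numeric(0)
  }
  rownames(res) <- NULL
  res
}

#' Substitution-class summary and frequency arithmetic
#'
#' `substitution_summary()` is the arithmetic core:
#' `ts_tv = n_ts / n_tv`, `snp_freq_bp = consensus_bp / (n_ts + n_tv)` (bp
#' of consensus per substitution SNP) and
#' `indel_freq_bp = consensus_bp / n_indel`. Reported companions are
#' truncated to the printed precision used in EST survey tables (2 dp for
#' the ratio, integer bp for frequencies); full precision is retained.
#' [summarize_substitutions()] derives the counts from a call set.
#'
#' @param n_ts transition count.
#' @param n_tv transversion count.
#' @param n_indel indel event count.
#' @param consensus_bp total consensus size in bp (> 0).
#' @return list of class `substitution_summary`.
#' @export
substitution_summary <- function(n_ts, n_tv, n_indel, consensus_bp) {
  if (consensus_bp <= 0) stopf("consensus_bp must be positive")
  n_subst <- n_ts + n_tv
  ts_tv <- if (n_tv > 0) n_ts / n_tv else NA_real_
  structure(list(
    n_ts = n_ts, n_tv = n_tv, n_indel = n_indel,
    n_snp_total = n_subst + n_indel, consensus_bp = consensus_bp,
    ts_tv_ratio = ts_tv,
    ts_tv_ratio_2dp = if (is.na(ts_tv)) NA_real_ else trunc_dp(ts_tv, 2),
    snp_freq_bp = if (n_subst > 0) consensus_bp / n_subst else NA_real_,
    snp_freq_bp_int = if (n_subst > 0) trunc(consensus_bp / n_subst)
                      else NA_real_,
    indel_freq_bp = if (n_indel > 0) consensus_bp / n_indel else NA_real_,
    indel_freq_bp_int = if (n_indel > 0) trunc(consensus_bp / n_indel)
                        else NA_real_
  ), class = "substitution_summary")
}

#' @export
print.substitution_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "substitutions: %d transitions, %d transversions, %d indels over %d bp\n",
    "  Ts/Tv %.2f  1 SNP/%s bp  1 indel/%s bp\n"),
    x$n_ts, x$n_tv, x$n_indel, x$consensus_bp,
    x$ts_tv_ratio_2dp,
    ifelse(is.na(x$snp_freq_bp_int), "-", x$snp_freq_bp_int),
    ifelse(is.na(x$indel_freq_bp_int), "-", x$indel_freq_bp_int)))
  invisible(x)
}

#' @rdname substitution_summary
#' @param calls SNP call data.frame.
#' @export
summarize_substitutions <- function(calls, consensus_bp) {
  substitution_summary(sum(calls$subst_class == "transition"),
                       sum(calls$subst_class == "transversion"),
                       sum(calls$kind == "indel"),
                       consensus_bp)
}

#' Write SNP calls as a minimal VCF 4.2 file
#'
#' The contig consensus acts as the reference; INFO carries the redundancy
#' (RED), co-segregation score (COSEG) and substitution class (CLASS).
#' Indel alleles are emitted symbolically as `*`.
#'
#' @param calls call data.frame (with `coseg` column).
#' @param cs the `cluster_set` the calls came from.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_snp_vcf <- function(calls, cs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=estminer",
               "##INFO=<ID=RED,Number=1,Type=Integer,Description=\"Minor allele redundancy\">",
               "##INFO=<ID=COSEG,Number=1,Type=Float,Description=\"Co-segregation score\">",
               "##INFO=<ID=CLASS,Number=1,Type=String,Description=\"ts, tv or indel\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(calls)) {
    ref <- mapply(function(cid, pos) {
      substr(cs$contigs[[cid]]$consensus, pos + 1, pos + 1)
    }, calls$contig_id, calls$pos)
    alt <- ifelse(calls$allele1 == ref, calls$allele2, calls$allele1)
    alt[alt == "-"] <- "*"
    cls <- c(transition = "ts", transversion = "tv", none = "indel")
    coseg <- if ("coseg" %in% names(calls)) calls$coseg else 0
    lines <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tRED=%d;COSEG=%.3f;CLASS=%s",
                     calls$contig_id, calls$pos + 1L, ref, alt,
                     calls$redundancy, coseg, cls[calls$subst_class])
    writeLines(lines, con)
  }
  invisible(path)
}
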