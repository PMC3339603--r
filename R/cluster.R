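#' Assemble a cluster set object
#'
#' A cluster set is the package's container for one library's assembly:
#' contigs (consensus plus member read placements) and singletons. It is the
#' substrate for the assembly summary indices and for SNP calling. Assembly
#' itself is an input (e.g. from CAP3); this constructor only validates and
#' normalises. A "contig" with a single member read is reclassified as a
#' singleton so that the contig/singleton arithmetic of the summary indices
#' stays consistent.
#'
#' @param contigs named list; each element is a list with `consensus`
#'   (character scalar) and `placements` (data.frame with read_id, strand,
#'   offset (0-based on consensus), aligned_seq where `-` marks a deletion).
#' @param singletons EST set data.frame (may have zero rows).
#' @param library library label.
#' @param n_input total input EST count; defaults to placements + singletons.
#' @return an object of class `cluster_set`.
#' @export
cluster_set <- function(contigs, singletons, library = "NA", n_input = NULL) {
  if (is.null(contigs)) contigs <- list()
  demote <- names(contigs)[vapply(contigs, function(ct)
    nrow(ct$placements) < 2, logical(1))]
  for (cid in demote) {
    pl <- contigs[[cid]]$placements
    if (nrow(pl) == 1) {
      seq <- gsub("-", "", pl$aligned_seq, fixed = TRUE)
      singletons <- rbind(singletons,
                          est_set(pl$read_id, seq, library))
    }
    contigs[[cid]] <- NULL
  }
  for (cid in names(contigs)) {
    ct <- contigs[[cid]]
    bad <- ct$placements$offset + nchar(ct$placements$aligned_seq) >
      nchar(ct$consensus)
    if (any(bad)) stopf("contig %s: read %s extends past consensus",
                        cid, ct$placements$read_id[which(bad)[1]])
  }
  n_member <- sum(vapply(contigs, function(ct) nrow(ct$placements), integer(1)))
  n_single <- if (is.null(singletons)) 0L else nrow(singletons)
  if (is.null(n_input)) n_input <- n_member + n_single
  structure(list(library = library, contigs = contigs,
                 singletons = singletons, n_input = n_input),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("cluster_set <%s>: %d input ESTs, %d contigs, %d singletons\n",
              x$library, x$n_input, length(x$contigs),
              if (is.null(x$singletons)) 0L else nrow(x$singletons)))
  invisible(x)
}

#' Library-level assembly summary indices
#'
#' `library_summary()` is the arithmetic core working from counts;
#' [summarize_library()] derives the counts from a cluster set. The
#' redundancy index is the percentage of input ESTs absorbed into contigs,
#' `100 * (n_input - n_singletons) / n_input`; the diversity index is the
#' percentage of the library represented by unique unigenes,
#' `100 * (n_contigs + n_singletons) / n_input`. Truncated values (see
#' [trunc_dp()]) are reported alongside full precision, plus a rounded
#' diversity variant since published tables have used either convention.
#'
#' @param n_input input EST count (> 0).
#' @param n_contigs number of contigs (>= 2 members each).
#' @param n_singletons number of unassembled ESTs.
#' @param mean_unigene_len optional mean unigene length in bp.
#' @return list of class `library_summary`.
#' @export
library_summary <- function(n_input, n_contigs, n_singletons,
                            mean_unigene_len = NA_real_) {
  if (n_input <= 0) stopf("n_input must be positive")
  n_unigenes <- n_contigs + n_singletons
  if (n_unigenes > n_input) stopf("more unigenes than input ESTs")
  red <- 100 * (n_input - n_singletons) / n_input
  div <- 100 * n_unigenes / n_input
  structure(list(
    n_input = n_input, n_contigs = n_contigs, n_singletons = n_singletons,
    n_unigenes = n_unigenes,
    redundancy_index = red, diversity_index = div,
    redundancy_index_2dp = trunc_dp(red, 2),
    diversity_index_1dp = trunc_dp(div, 1),
    diversity_index_rounded = round(div),
    mean_unigene_len = mean_unigene_len
  ), class = "library_summary")
}

#' @export
print.library_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "library summary: %d ESTs -> %d contigs + %d singletons (%d unigenes)\n",
    "  redundancy index %.2f%%  diversity index %.1f%%\n"),
    x$n_input, x$n_contigs, x$n_singletons, x$n_unigenes,
    x$redundancy_index_2dp, x$diversity_index_1dp))
  invisible(x)
}

#' Summarise a cluster set
#'
#' @param cs a `cluster_set`.
#' @return a `library_summary` (see [library_summary()]).
#' @export
summarize_library <- function(cs) {
  stopifnot(inherits(cs, "cluster_set"))
  if (cs$n_input == 0) stopf("empty cluster set")
  n_single <- if (is.null(cs$singletons)) 0L else nrow(cs$singletons)
  lens <- c(vapply(cs$contigs, function(ct) nchar(ct$consensus), integer(1)),
            if (n_single) cs$singletons$length else integer(0))
  library_summary(cs$n_input, length(cs$contigs), n_single,
                  mean_unigene_len = if (length(lens)) mean(lens) else NA_real_)
}

#' Percentage of sequences that carry at least one SSR
#'
#' @param n_seqs number of sequences screened (> 0).
#' @param n_ssr_seqs number of those carrying an SSR.
#' @return percentage at full precision (truncate for reporting).
#' @export
ssr_est_rate <- function(n_seqs, n_ssr_seqs) {
  if (n_seqs <= 0) stopf("n_seqs must be positive")
  if (n_ssr_seqs < 0 || n_ssr_seqs > n_seqs) stopf("invalid SSR sequence count")
  100 * n_ssr_seqs / n_seqs
}

# best ungapped overlap between two sequences; returns list(offset, len, ident)
# for the highest-identity overlap of length >= min_overlap, or NULL.
# offset is the start of b relative to a (may be negative).
best_overlap <- function(a, b, min_overlap, min_identity) {
  ca <- seq_chars(a); cb <- seq_chars(b)
  na <- length(ca); nb <- length(cb)
  best <- NULL
  for (off in seq(-(nb - min_overlap), na - min_overlap)) {
    lo <- max(1L, off + 1L); hi <- min(na, off + nb)
    len <- hi - lo + 1L
    if (len < min_overlap) next
    ia <- lo:hi; ib <- (lo - off):(hi - off)
    ident <- mean(ca[ia] == cb[ib])
    if (ident >= min_identity &&
        (is.null(best) || len * ident > best$len * best$ident)) {
      best <- list(offset = off, len = len, ident = ident)
    }
  }
  best
}

#' Naive greedy overlap clustering (test stand-in for a real assembler)
#'
#' Deterministic single-linkage clustering on ungapped exact overlaps. This
#' is not an assembler: it exists so that synthetic libraries can be pushed
#' through the full pipeline without external tools, and it is quadratic in
#' the number of reads. Consensus is per-column majority with alphabetical
#' tie-break.
#'
#' @param ests EST set data.frame.
#' @param min_overlap minimum ungapped overlap length (nt).
#' @param min_identity minimum identity fraction over the overlap.
#' @return a `cluster_set`.
#' @export
greedy_overlap_cluster <- function(ests, min_overlap = 40,
                                   min_identity = 0.95) {
  n <- nrow(ests)
  if (!n) stopf("no sequences")
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  rel <- vector("list", n)  # adjacency with relative offsets
  for (i in seq_len(n)) rel[[i]] <- list()
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      ov <- best_overlap(ests$seq[i], ests$seq[j], min_overlap, min_identity)
      if (!is.null(ov)) {
        rel[[i]][[length(rel[[i]]) + 1]] <- c(j, ov$offset)
        rel[[j]][[length(rel[[j]]) + 1]] <- c(i, -ov$offset)
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  contigs <- list(); singles <- integer(0); k <- 0L
  for (root in sort(unique(comp))) {
    members <- which(comp == root)
    if (length(members) == 1) { singles <- c(singles, members); next }
    # BFS offsets anchored at the first member
    offset <- stats::setNames(rep(NA_integer_, length(members)),
                              as.character(members))
    offset[as.character(members[1])] <- 0L
    queue <- members[1]
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      for (e in rel[[u]]) {
        v <- e[1]
        if (v %in% members && is.na(offset[as.character(v)])) {
          offset[as.character(v)] <- offset[as.character(u)] + e[2]
          queue <- c(queue, v)
        }
      }
    }
    off <- offset[as.character(members)] - min(offset, na.rm = TRUE)
    width <- max(off + ests$length[members])
    mat <- matrix(NA_character_, length(members), width)
    for (m in seq_along(members)) {
      ch <- seq_chars(ests$seq[members[m]])
      mat[m, (off[m] + 1):(off[m] + length(ch))] <- ch
    }
    cons <- apply(mat, 2, function(col) {
      col <- col[!is.na(col) & col != "-"]
      if (!length(col)) return("N")
      tab <- sort(table(col), decreasing = TRUE)
      names(tab)[tab == max(tab)][1]  # alphabetical tie-break via sort below
    })
    # alphabetical tie-break: recompute deterministically
    cons <- apply(mat, 2, function(col) {
      col <- col[!is.na(col) & col != "-"]
      if (!length(col)) return("N")
      tab <- table(col)
      cand <- names(tab)[tab == max(tab)]
      sort(cand)[1]
    })
    k <- k + 1L
    contigs[[sprintf("contig%04d", k)]] <- list(
      consensus = paste(cons, collapse = ""),
      placements = data.frame(read_id = ests$id[members], strand = "+",
                              offset = unname(off),
                              aligned_seq = ests$seq[members],
                              stringsAsFactors = FALSE))
  }
  cluster_set(contigs, ests[singles, , drop = FALSE],
              library = ests$library[1], n_input = n)
}

#' Read and write cluster membership tables
#'
#' The interchange format is a TSV with columns contig_id, read_id, strand,
#' offset (0-based on the consensus) and aligned_seq (gapped read in contig
#' coordinates, `-` for deletion). The consensus is rebuilt by per-column
#' majority over the member reads (alphabetical tie-break, all-gap columns
#' emit N), so round-trips are self-contained.
#'
#' @param path TSV file.
#' @param singletons optional EST set of unassembled reads.
#' @param library library label.
#' @param n_input optional total input count.
#' @return `read_cluster_tsv()` returns a `cluster_set`;
#'   `write_cluster_tsv()` returns `path` invisibly.
#' @export
read_cluster_tsv <- function(path, singletons = NULL, library = "NA",
                             n_input = NULL) {
  df <- read_tsv(path)
  need <- c("contig_id", "read_id", "strand", "offset", "aligned_seq")
  if (!all(need %in% names(df))) stopf("cluster TSV needs columns: %s",
                                       paste(need, collapse = ", "))
  contigs <- lapply(split(df, df$contig_id), function(d) {
    width <- max(d$offset + nchar(d$aligned_seq))
    mat <- matrix(NA_character_, nrow(d), width)
    for (m in seq_len(nrow(d))) {
      ch <- seq_chars(d$aligned_seq[m])
      mat[m, (d$offset[m] + 1):(d$offset[m] + length(ch))] <- ch
    }
    cons <- apply(mat, 2, function(col) {
      col <- col[!is.na(col) & col != "-"]
      if (!length(col)) return("N")
      tab <- table(col)
      sort(names(tab)[tab == max(tab)])[1]
    })
    list(consensus = paste(cons, collapse = ""),
         placements = d[, c("read_id", "strand", "offset", "aligned_seq")])
  })
  if (is.null(singletons))
    singletons <- est_set("placeholder", "ACGT", library)[0, ]
  cluster_set(contigs, singletons, library, n_input)
}

#' @rdname read_cluster_tsv
#' @param cs a `cluster_set`.
#' @export
write_cluster_tsv <- function(cs, path) {
  rows <- lapply(names(cs$contigs), function(cid) {
    pl <- cs$contigs[[cid]]$placements
    cbind(contig_id = cid, pl)
  })
  df <- do.call(rbind, rows)
  write_tsv(df, path)
}
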