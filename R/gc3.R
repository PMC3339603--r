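#' Codon position-specific nucleotide composition
#'
#' Computes GC1, GC2, GC3 -- the G+C fraction at each of the three codon
#' positions -- plus the overall GC fraction, over the complete codons of a
#' coding sequence. N residues are excluded position-wise from both
#' numerator and denominator.
#'
#' @param seq coding sequence (nucleotide string).
#' @param frame_offset 0, 1 or 2 nt skipped before the first codon.
#' @param seq_id optional identifier.
#' @return one-row data.frame: seq_id, n_codons, gc1, gc2, gc3, gc, length.
#' @export
codon_composition <- function(seq, frame_offset = 0, seq_id = NA_character_) {
  n <- nchar(seq)
  n_codons <- (n - frame_offset) %/% 3
  if (n_codons < 1) stopf("fewer than one full codon")
  ch <- seq_chars(seq)[(frame_offset + 1):(frame_offset + 3 * n_codons)]
  posk <- rep(1:3, n_codons)
  counted <- ch != "N"
  isgc <- ch %in% c("G", "C")
  gck <- vapply(1:3, function(k) {
    idx <- posk == k & counted
    if (!any(idx)) return(NaN)
    sum(isgc[idx]) / sum(idx)
  }, numeric(1))
  data.frame(seq_id = seq_id, n_codons = n_codons,
             gc1 = gck[1], gc2 = gck[2], gc3 = gck[3],
             gc = if (any(counted)) sum(isgc[counted]) / sum(counted) else NaN,
             length = n, stringsAsFactors = FALSE)
}

#' Codon composition for a set of coding sequences
#'
#' @param cds named character vector of sequences, or a data.frame with
#'   `id`/`seq_id` and `seq` columns.
#' @param frame_offset passed to [codon_composition()].
#' @return data.frame with one row per sequence.
#' @export
codon_composition_set <- function(cds, frame_offset = 0) {
  if (is.data.frame(cds)) {
    ids <- if ("seq_id" %in% names(cds)) cds$seq_id else cds$id
    seqs <- cds$seq
  } else {
    ids <- names(cds); seqs <- unname(cds)
  }
  out <- do.call(rbind, lapply(seq_along(seqs), function(i)
    codon_composition(seqs[i], frame_offset, ids[i])))
  rownames(out) <- NULL
  out
}

#' Top and bottom GC3 fractions of a gene set
#'
#' Selects the `fraction` (default 10%) of genes with the highest and with
#' the lowest GC3. Set sizes are `ceiling(fraction * n)`; ties are broken by
#' seq_id for determinism; the two sets are guaranteed disjoint.
#'
#' @param comps data.frame from [codon_composition_set()].
#' @param fraction tail fraction in (0, 0.5].
#' @return list with `high` and `low` character vectors of seq_ids.
#' @export
gc3_deciles <- function(comps, fraction = 0.10) {
  n <- nrow(comps)
  if (n < 10) stopf("too few genes")
  if (fraction <= 0 || fraction > 0.5) stopf("fraction must be in (0, 0.5]")
  k <- ceiling(fraction * n)
  if (2 * k > n) stopf("tail sets would overlap")
  ord_hi <- order(-comps$gc3, comps$seq_id)
  ord_lo <- order(comps$gc3, comps$seq_id)
  high <- comps$seq_id[ord_hi[seq_len(k)]]
  low <- setdiff(comps$seq_id[ord_lo], high)[seq_len(k)]
  list(high = high, low = low)
}

#' Chi-square GO-term enrichment between high- and low-GC3 gene sets
#'
#' For every GO term annotated to at least one gene of either set, builds
#' the 2x2 table (in term vs not, high vs low) and applies a chi-square test
#' with one degree of freedom, by default without Yates continuity
#' correction. Rows are sorted by descending high/low ratio. No
#' multiple-testing correction is applied unless `fdr = TRUE`, which adds a
#' Benjamini-Hochberg adjusted column.
#'
#' @param high,low character vectors of gene ids.
#' @param annotations data.frame with gene_id, go_id and optionally
#'   description and ontology columns.
#' @param alpha significance level.
#' @param correct apply Yates continuity correction.
#' @param fdr add a BH-adjusted p-value column.
#' @return data.frame: go_id, description, ontology, n_high, n_low, ratio,
#'   chi2_stat, p_value, significant (and p_adj when `fdr`).
#' @export
go_enrichment <- function(high, low, annotations, alpha = 0.05,
                          correct = FALSE, fdr = FALSE) {
  ann <- annotations[annotations$gene_id %in% c(high, low), , drop = FALSE]
  if (!nrow(ann)) stopf("annotations cover no gene in either set")
  nh_tot <- length(high); nl_tot <- length(low)
  terms <- unique(ann$go_id)
  rows <- lapply(terms, function(g) {
    genes <- unique(ann$gene_id[ann$go_id == g])
    n_high <- sum(high %in% genes)
    n_low <- sum(low %in% genes)
    if (n_high + n_low == 0) return(NULL)
    m <- matrix(c(n_high, nh_tot - n_high, n_low, nl_tot - n_low), nrow = 2)
    test <- tryCatch(
      suppressWarnings(stats::chisq.test(m, correct = correct)),
      error = function(e) NULL)
    chi2 <- if (is.null(test)) NA_real_ else unname(test$statistic)
    p <- if (is.null(test)) NA_real_ else test$p.value
    desc <- if ("description" %in% names(ann))
      ann$description[ann$go_id == g][1] else NA_character_
    onto <- if ("ontology" %in% names(ann))
      ann$ontology[ann$go_id == g][1] else NA_character_
    data.frame(go_id = g, description = desc, ontology = onto,
               n_high = n_high, n_low = n_low,
               ratio = if (n_low > 0) n_high / n_low else NA_real_,
               chi2_stat = chi2, p_value = p,
               significant = !is.na(p) && p < alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stopf("no term annotated in either set")
  out <- out[order(-out$ratio, out$go_id, na.last = TRUE), , drop = FALSE]
  if (fdr) out$p_adj <- stats::p.adjust(out$p_value, "BH")
  rownames(out) <- NULL
  out
}

#' Mode profile of a GC3 distribution
#'
#' Descriptive utility for inspecting unimodality of the GC3 histogram via a
#' kernel density estimate: reports the number of local modes and the depth
#' of the deepest valley between the two tallest modes relative to the lower
#' of the two (0 when unimodal). It asserts nothing and feeds no test.
#'
#' @param gc3 numeric vector of per-gene GC3 values.
#' @param bw kernel bandwidth passed to [stats::density()].
#' @return list with n_modes and valley_depth.
#' @export
gc3_mode_profile <- function(gc3, bw = "nrd0") {
  d <- stats::density(gc3, bw = bw, from = 0, to = 1, n = 512)
  y <- d$y
  peak <- which(diff(sign(diff(y))) == -2) + 1
  if (length(peak) < 2) return(list(n_modes = length(peak), valley_depth = 0))
  top2 <- peak[order(-y[peak])][1:2]
  lo <- min(top2); hi <- max(top2)
  valley <- min(y[lo:hi])
  list(n_modes = length(peak),
       valley_depth = (min(y[top2]) - valley) / min(y[top2]))
}
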