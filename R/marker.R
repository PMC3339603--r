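# standard genetic code lookup, codon -> single-letter amino acid ("*" stop)
codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
}

.estminer_codons <- local({
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
})

# translate a nucleotide string in one forward frame; codons with N become X
translate_frame <- function(seq, offset) {
  n <- nchar(seq)
  n_codon <- (n - offset) %/% 3
  if (n_codon < 1) return(character(0))
  starts <- offset + 1 + 3 * (seq_len(n_codon) - 1)
  codons <- substring(seq, starts, starts + 2)
  aa <- .estminer_codons[codons]
  aa[is.na(aa)] <- "X"
  unname(aa)
}

#' Longest stop-free reading frame over six frames
#'
#' Translates the sequence in all six frames with the standard genetic code
#' and returns the longest stretch of codons uninterrupted by a stop. No ATG
#' initiator is required by default (set `require_atg = TRUE` to anchor the
#' stretch at its first ATG codon). Ties are broken by frame order +1, +2,
#' +3, -1, -2, -3 and then by leftmost forward-strand start. Coordinates are
#' always reported on the forward strand, 0-based half-open.
#'
#' @param seq nucleotide string (>= 3 nt).
#' @param seq_id optional identifier carried through.
#' @param require_atg if TRUE, the reported stretch starts at an ATG.
#' @return list with seq_id, frame (+1..+3, -1..-3), start, end, aa_len,
#'   protein.
#' @export
longest_orf_six_frames <- function(seq, seq_id = NA_character_,
                                   require_atg = FALSE) {
  n <- nchar(seq)
  if (n < 3) stopf("sequence shorter than one codon")
  frames <- list(c(1, 0), c(1, 1), c(1, 2), c(-1, 0), c(-1, 1), c(-1, 2))
  rcseq <- revcomp(seq)
  best <- NULL
  for (fi in seq_along(frames)) {
    strand <- frames[[fi]][1]; off <- frames[[fi]][2]
    s <- if (strand == 1) seq else rcseq
    aa <- translate_frame(s, off)
    if (!length(aa)) next
    runs <- rle(aa != "*")
    pos <- cumsum(c(1L, runs$lengths))
    for (j in which(runs$values)) {
      c0 <- pos[j]                       # first codon (1-based) of the run
      len <- runs$lengths[j]
      prot <- paste(aa[c0:(c0 + len - 1)], collapse = "")
      if (require_atg) {
        codon_starts <- off + 1 + 3 * ((c0:(c0 + len - 1)) - 1)
        codons <- substring(s, codon_starts, codon_starts + 2)
        m <- which(codons == "ATG")
        if (!length(m)) next
        c0 <- c0 + m[1] - 1
        len <- len - m[1] + 1
        prot <- substr(prot, m[1], nchar(prot))
      }
      nt_start <- off + 3 * (c0 - 1)     # 0-based on the translated strand
      nt_end <- nt_start + 3 * len
      if (strand == 1) {
        fwd <- c(nt_start, nt_end)
      } else {
        fwd <- c(n - nt_end, n - nt_start)
      }
      cand <- list(seq_id = seq_id,
                   frame = strand * (off + 1),
                   start = fwd[1], end = fwd[2], aa_len = len,
                   protein = prot, frame_order = fi)
      if (is.null(best) ||
          cand$aa_len > best$aa_len ||
          (cand$aa_len == best$aa_len &&
           (cand$frame_order < best$frame_order ||
            (cand$frame_order == best$frame_order &&
             cand$start < best$start)))) best <- cand
    }
  }
  if (is.null(best)) {
    best <- list(seq_id = seq_id, frame = 1L, start = 0L, end = 0L,
                 aa_len = 0L, protein = "", frame_order = 1L)
  }
  best$frame_order <- NULL
  best
}

#' Classify an SSR as inside or outside the predicted ORF
#'
#' By default any overlap of at least one nucleotide with the ORF's
#' forward-strand interval counts as ORF-located; `mode = "contain"`
#' requires the SSR to lie entirely within the ORF.
#'
#' @param ssr_start,ssr_end SSR interval, 0-based half-open.
#' @param orf an ORF call from [longest_orf_six_frames()].
#' @param mode "overlap" (default) or "contain".
#' @return "ORF" or "non-ORF".
#' @export
classify_ssr_location <- function(ssr_start, ssr_end, orf,
                                  mode = c("overlap", "contain")) {
  mode <- match.arg(mode)
  inside <- if (mode == "overlap") {
    ssr_start < orf$end && ssr_end > orf$start
  } else {
    ssr_start >= orf$start && ssr_end <= orf$end
  }
  if (orf$aa_len == 0) inside <- FALSE
  if (inside) "ORF" else "non-ORF"
}

#' Primer melting temperature (deterministic approximation)
#'
#' Wallace rule (2 degC per A/T, 4 per G/C) below 14 nt, otherwise the
#' GC-fraction formula 64.9 + 41 * (n_GC - 16.4) / length. This is the
#' documented dependency-free default; pass a different `tm_fun` to
#' [design_primer_candidates()] to use another thermodynamic model.
#'
#' @param seq primer sequence(s).
#' @return melting temperature(s) in degrees C.
#' @export
primer_tm <- function(seq) {
  vapply(seq, function(s) {
    ch <- seq_chars(s)
    ngc <- sum(ch %in% c("G", "C"))
    len <- length(ch)
    if (len < 14) 2 * (len - ngc) + 4 * ngc
    else 64.9 + 41 * (ngc - 16.4) / len
  }, numeric(1), USE.NAMES = FALSE)
}

#' Primer design constraints
#'
#' @param size_range allowed primer lengths (nt).
#' @param size_opt optimum primer length.
#' @param tm_range allowed melting temperature window (degC).
#' @param tm_opt optimum melting temperature.
#' @param gc_range allowed GC percentage window.
#' @param product_range allowed amplicon size (bp).
#' @return list of constraints for [design_primer_candidates()].
#' @export
primer_constraints <- function(size_range = c(18, 27), size_opt = 20,
                               tm_range = c(57, 63), tm_opt = 60,
                               gc_range = c(20, 80),
                               product_range = c(100, 400)) {
  list(size_range = size_range, size_opt = size_opt, tm_range = tm_range,
       tm_opt = tm_opt, gc_range = gc_range, product_range = product_range)
}

# enumerate all candidate windows on one flank; side "left" uses the window
# as-is, side "right" takes the reverse complement
flank_candidates <- function(seq, lo, hi, cfg, tm_fun) {
  lens <- cfg$size_range[1]:cfg$size_range[2]
  rows <- list()
  for (len in lens) {
    if (hi - lo + 1 < len) next
    starts <- lo:(hi - len + 1)
    win <- substring(seq, starts, starts + len - 1)
    rows[[length(rows) + 1]] <- data.frame(
      start = starts, len = len, seq = win, stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(NULL)
  cand <- do.call(rbind, rows)
  cand$has_n <- grepl("N", cand$seq, fixed = TRUE)
  ch_gc <- nchar(gsub("[^GC]", "", cand$seq))
  cand$gc <- 100 * ch_gc / cand$len
  cand$tm <- tm_fun(cand$seq)
  cand
}

#' Design a locus-specific primer pair flanking an SSR
#'
#' Exhaustively scans both flanks with windows of every allowed length,
#' discards windows containing N or violating the GC and Tm windows, and
#' returns the admissible pair minimising the penalty
#' `|len - size_opt| + |tm - tm_opt|` summed over both primers, subject to
#' the product-size range. The right primer is the reverse complement of its
#' window. On failure the constraint that eliminated all candidates is
#' reported.
#'
#' @param seq the template sequence.
#' @param ssr_start,ssr_end SSR interval, 0-based half-open.
#' @param cfg constraints from [primer_constraints()].
#' @param tm_fun melting-temperature function (default [primer_tm()]).
#' @return list with status "ok" (left/right data, product_len, penalty) or
#'   status "fail" with a reason code.
#' @export
design_primer_candidates <- function(seq, ssr_start, ssr_end,
                                     cfg = primer_constraints(),
                                     tm_fun = primer_tm) {
  n <- nchar(seq)
  min_len <- cfg$size_range[1]
  if (ssr_start < min_len || n - ssr_end < min_len) {
    return(list(status = "fail", reason = "flank_too_short"))
  }
  left <- flank_candidates(seq, 1L, ssr_start, cfg, tm_fun)
  right <- flank_candidates(seq, ssr_end + 1L, n, cfg, tm_fun)
  filter_side <- function(cand) {
    if (is.null(cand)) return(list(ok = NULL, reason = "flank_too_short"))
    fail_n <- cand$has_n
    fail_gc <- cand$gc < cfg$gc_range[1] | cand$gc > cfg$gc_range[2]
    fail_tm <- cand$tm < cfg$tm_range[1] | cand$tm > cfg$tm_range[2]
    ok <- cand[!(fail_n | fail_gc | fail_tm), , drop = FALSE]
    if (nrow(ok)) return(list(ok = ok, reason = ""))
    # report the constraint that rejected the most windows
    counts <- c(contains_n = sum(fail_n), gc_out_of_range = sum(fail_gc),
                tm_out_of_range = sum(fail_tm))
    list(ok = NULL, reason = names(which.max(counts)))
  }
  fl <- filter_side(left); fr <- filter_side(right)
  if (is.null(fl$ok)) return(list(status = "fail", reason = fl$reason))
  if (is.null(fr$ok)) return(list(status = "fail", reason = fr$reason))
  L <- fl$ok; R <- fr$ok
  pen_l <- abs(L$len - cfg$size_opt) + abs(L$tm - cfg$tm_opt)
  pen_r <- abs(R$len - cfg$size_opt) + abs(R$tm - cfg$tm_opt)
  # product = right window end - left window start (1-based inclusive span)
  prod <- outer(L$start, R$start + R$len - 1, function(a, b) b - a + 1)
  pen <- outer(pen_l, pen_r, `+`)
  admissible <- prod >= cfg$product_range[1] & prod <= cfg$product_range[2]
  if (!any(admissible)) return(list(status = "fail",
                                    reason = "no_product_in_range"))
  pen[!admissible] <- Inf
  best <- which(pen == min(pen), arr.ind = TRUE)
  # deterministic tie-break: leftmost left start, then leftmost right start
  ordb <- order(L$start[best[, 1]], R$start[best[, 2]])
  bi <- best[ordb[1], 1]; bj <- best[ordb[1], 2]
  list(status = "ok",
       left = list(side = "left", seq = L$seq[bi], start = L$start[bi] - 1L,
                   len = L$len[bi], tm = L$tm[bi], gc = L$gc[bi]),
       right = list(side = "right", seq = revcomp(R$seq[bj]),
                    start = R$start[bj] - 1L, len = R$len[bj],
                    tm = R$tm[bj], gc = R$gc[bj]),
       product_len = prod[bi, bj], penalty = pen[bi, bj])
}

#' Project a protein-coordinate domain interval onto the forward strand
#'
#' Protein position p (0-based) of an ORF in a forward frame occupies
#' nucleotides `[orf_start + 3p, orf_start + 3p + 3)`; reverse-frame ORFs
#' are mapped through the ORF's forward-strand interval accordingly.
#'
#' @param orf an ORF call.
#' @param p_start,p_end protein interval, 0-based half-open.
#' @return integer vector `c(start, end)`, 0-based half-open on the forward
#'   strand.
#' @export
project_domain_to_nt <- function(orf, p_start, p_end) {
  if (p_start < 0 || p_end > orf$aa_len) stopf("domain outside protein")
  if (orf$frame > 0) {
    c(orf$start + 3 * p_start, orf$start + 3 * p_end)
  } else {
    c(orf$end - 3 * p_end, orf$end - 3 * p_start)
  }
}

#' Call SSR functional-domain markers (SSR-FDMs)
#'
#' An SSR-FDM is a sequence carrying both an SSR and an annotated protein
#' domain in its predicted ORF. The default sequence-level mode reports all
#' (SSR, domain) pairs on such sequences; the strict mode additionally
#' requires the nucleotide projection of the domain interval to overlap the
#' SSR.
#'
#' @param ssrs SSR hit data.frame for one sequence.
#' @param orf the sequence's ORF call.
#' @param domains data.frame with domain_id, description, start, end
#'   (0-based half-open protein coordinates).
#' @param mode "sequence" or "overlap".
#' @return data.frame of pairs: seq_id, ssr unit/start/end, domain_id,
#'   description, domain nt interval.
#' @export
call_ssr_fdm <- function(ssrs, orf, domains,
                         mode = c("sequence", "overlap")) {
  mode <- match.arg(mode)
  empty <- data.frame(seq_id = character(0), unit = character(0),
                      ssr_start = integer(0), ssr_end = integer(0),
                      domain_id = character(0), description = character(0),
                      dom_nt_start = integer(0), dom_nt_end = integer(0),
                      stringsAsFactors = FALSE)
  if (!nrow(ssrs) || is.null(domains) || !nrow(domains)) return(empty)
  rows <- list()
  for (i in seq_len(nrow(ssrs))) for (j in seq_len(nrow(domains))) {
    nt <- project_domain_to_nt(orf, domains$start[j], domains$end[j])
    if (mode == "overlap" &&
        !(ssrs$start[i] < nt[2] && ssrs$end[i] > nt[1])) next
    rows[[length(rows) + 1]] <- data.frame(
      seq_id = ssrs$seq_id[i], unit = ssrs$unit[i],
      ssr_start = ssrs$start[i], ssr_end = ssrs$end[i],
      domain_id = domains$domain_id[j],
      description = domains$description[j],
      dom_nt_start = nt[1], dom_nt_end = nt[2], stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
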