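# random DNA string(s) with a target GC fraction
rand_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

# independent certification scanner: regex enumeration of every unit length,
# used only to certify that generated sequence is free of incidental repeats
# at or above the detection thresholds
has_incidental_ssr <- function(seq, minrep = c(14, 7, 5, 4, 4, 3)) {
  for (k in 1:6) {
    pat <- sprintf("([ACGT]{%d})\\1{%d,}", k, minrep[k] - 1)
    if (grepl(pat, seq, perl = TRUE)) return(TRUE)
  }
  FALSE
}

#' SSR planting specification
#'
#' @param fraction fraction of transcripts that receive one planted SSR.
#' @param units pool of repeat units sampled uniformly.
#' @param extra_repeats 0-based extra copies beyond the class threshold,
#'   sampled uniformly from `0:extra_repeats`.
#' @return list consumed by [make_est_library()].
#' @export
ssr_spec <- function(fraction = 0.10,
                     units = c("AT", "AG", "CT", "AC", "AAG", "ATC", "CCG",
                               "AAAG", "ACGTG", "AACGTC"),
                     extra_repeats = 4) {
  list(fraction = fraction, units = units, extra_repeats = extra_repeats)
}

#' SNP planting specification
#'
#' @param p_snp per-base probability that a transcript position is
#'   polymorphic between the two haplotypes.
#' @param p_transition probability that a substitution is a transition.
#' @param indel_fraction fraction of variant positions that are 1-nt
#'   deletions in the second haplotype instead of substitutions.
#' @return list consumed by [make_est_library()].
#' @export
snp_spec <- function(p_snp = 0.01, p_transition = 0.5,
                     indel_fraction = 0.05) {
  list(p_snp = p_snp, p_transition = p_transition,
       indel_fraction = indel_fraction)
}

.ssr_minrep <- c(`1` = 14, `2` = 7, `3` = 5, `4` = 4, `5` = 4, `6` = 3)

# plant one SSR into a repeat-free transcript; retries until the planted run
# scans exactly as specified and nothing else scans (certified ground truth)
plant_ssr_transcript <- function(tlen, gc, unit, n_repeats, max_tries = 60) {
  k <- nchar(unit)
  ins <- strrep(unit, n_repeats)
  for (try in seq_len(max_tries)) {
    body <- rand_dna(tlen - nchar(ins), gc)
    pos <- sample(seq(40, nchar(body) - 40), 1)   # keep flanks usable
    seq <- paste0(substr(body, 1, pos), ins,
                  substr(body, pos + 1, nchar(body)))
    hits <- scan_ssr_seq(seq, .ssr_minrep)
    if (nrow(hits) == 1 && hits$unit_len == k &&
        hits$n_repeats == n_repeats && hits$start == pos &&
        canonical_rotation(hits$unit) == canonical_rotation(unit)) {
      return(list(seq = seq, start = pos, end = pos + k * n_repeats,
                  unit = substr(seq, pos + 1, pos + k)))
    }
  }
  stopf("could not place SSR %s x%d without collisions", unit, n_repeats)
}

transition_of <- c(A = "G", G = "A", C = "T", T = "C")
transversions_of <- list(A = c("C", "T"), G = c("C", "T"),
                         C = c("A", "G"), T = c("A", "G"))

#' Simulate an EST library with planted ground truth
#'
#' Generates transcripts, plants perfect SSRs in certified repeat-free
#' context, assigns two haplotypes per transcript with planted biallelic
#' substitutions (transition probability `snp$p_transition`) and 1-nt
#' deletions, samples reads with random offsets (giving the true cluster
#' set), applies optional sequencing errors, and appends 3' poly-A tails to
#' a fraction of reads. Everything is driven by `seed`: the same seed
#' reproduces the library byte for byte.
#'
#' Default shape loosely follows a fruit EST library: a few thousand
#' transcripts of ~520 bp mean sampled to about 1.3 reads each, which
#' yields the characteristic mix of contigs and a large singleton fraction.
#'
#' @param n_transcripts number of transcripts.
#' @param read_lambda reads per transcript are `1 + Poisson(read_lambda)`.
#' @param transcript_len mean and sd of transcript length (nt).
#' @param read_len uniform read-length range (nt), clipped to the
#'   transcript.
#' @param gc transcript G+C fraction.
#' @param error_rate per-base sequencing error probability in reads.
#' @param ssr an [ssr_spec()].
#' @param snp a [snp_spec()].
#' @param polya_fraction fraction of reads receiving a 3' poly-A tail.
#' @param polya_len uniform tail-length range (nt).
#' @param library library label.
#' @param seed RNG seed (required; the generator is seed-deterministic).
#' @return list with `ests` (reads as an EST set), `clusters` (the true
#'   `cluster_set`), and `truth` (planted_ssrs, planted_snps, transcripts,
#'   reads, params).
#' @export
make_est_library <- function(n_transcripts = 300, read_lambda = 0.34,
                             transcript_len = c(520, 120),
                             read_len = c(250, 600), gc = 0.45,
                             error_rate = 0,
                             ssr = ssr_spec(), snp = snp_spec(),
                             polya_fraction = 0.25, polya_len = c(12, 30),
                             library = "SYN", seed) {
  if (missing(seed)) stopf("seed is required")
  set.seed(seed)
  tids <- sprintf("T%05d", seq_len(n_transcripts))
  tlen <- pmax(200L, round(stats::rnorm(n_transcripts, transcript_len[1],
                                        transcript_len[2])))
  with_ssr <- stats::runif(n_transcripts) < ssr$fraction
  planted_ssrs <- list()
  transcripts <- character(n_transcripts)
  for (t in seq_len(n_transcripts)) {
    if (with_ssr[t]) {
      unit <- sample(ssr$units, 1)
      k <- nchar(unit)
      nrep <- .ssr_minrep[[as.character(k)]] +
        sample(0:ssr$extra_repeats, 1)
      pl <- plant_ssr_transcript(tlen[t], gc, unit, nrep)
      transcripts[t] <- pl$seq
      planted_ssrs[[length(planted_ssrs) + 1]] <- data.frame(
        seq_id = tids[t], unit = pl$unit, n_repeats = nrep,
        start = pl$start, end = pl$end, stringsAsFactors = FALSE)
    } else {
      repeat {
        s <- rand_dna(tlen[t], gc)
        if (!has_incidental_ssr(s)) break
      }
      transcripts[t] <- s
    }
  }
  tlen <- nchar(transcripts)
  n_reads_t <- 1L + stats::rpois(n_transcripts, read_lambda)

  # haplotype variants for transcripts that will form contigs
  planted_snps <- list()
  hap_variants <- vector("list", n_transcripts)   # data.frame pos/ref/alt
  for (t in seq_len(n_transcripts)) {
    if (n_reads_t[t] < 2 || snp$p_snp <= 0) next
    pos <- which(stats::runif(tlen[t]) < snp$p_snp)
    if (with_ssr[t] && length(pos)) {
      ps <- planted_ssrs[[sum(with_ssr[1:t])]]
      pos <- pos[pos <= ps$start | pos > ps$end]   # keep repeats intact
    }
    # avoid adjacent variants so indel events stay single-column
    if (length(pos) > 1) pos <- pos[c(TRUE, diff(pos) > 1)]
    if (!length(pos)) next
    ref <- substring(transcripts[t], pos, pos)
    is_indel <- stats::runif(length(pos)) < snp$indel_fraction
    is_ts <- !is_indel & stats::runif(length(pos)) < snp$p_transition
    alt <- character(length(pos))
    alt[is_indel] <- "-"
    alt[is_ts] <- transition_of[ref[is_ts]]
    tv <- !is_indel & !is_ts
    alt[tv] <- vapply(ref[tv], function(b)
      sample(transversions_of[[b]], 1), character(1))
    hap_variants[[t]] <- data.frame(pos = pos - 1L, ref = ref, alt = alt,
                                    is_transition = is_ts,
                                    is_indel = is_indel,
                                    stringsAsFactors = FALSE)
  }

  # sample reads
  reads <- list(); contigs <- list(); singleton_rows <- list()
  for (t in seq_len(n_transcripts)) {
    nr <- n_reads_t[t]
    hap <- rep(c(1L, 2L), length.out = nr)
    rl <- pmin(tlen[t],
               round(stats::runif(nr, read_len[1], read_len[2])))
    off <- vapply(rl, function(l)
      sample(0:(tlen[t] - l), 1), integer(1))
    ref_chars <- seq_chars(transcripts[t])
    placements <- vector("list", nr)
    for (r in seq_len(nr)) {
      ch <- ref_chars[(off[r] + 1):(off[r] + rl[r])]
      hv <- hap_variants[[t]]
      if (hap[r] == 2L && !is.null(hv)) {
        inside <- hv$pos >= off[r] & hv$pos < off[r] + rl[r]
        if (any(inside)) ch[hv$pos[inside] - off[r] + 1] <- hv$alt[inside]
      }
      if (error_rate > 0) {
        hit <- which(stats::runif(rl[r]) < error_rate & ch != "-")
        for (e in hit) ch[e] <- sample(setdiff(c("A", "C", "G", "T"), ch[e]), 1)
      }
      aligned <- paste(ch, collapse = "")
      read_seq <- gsub("-", "", aligned, fixed = TRUE)
      if (stats::runif(1) < polya_fraction) {
        read_seq <- paste0(read_seq,
                           strrep("A", sample(polya_len[1]:polya_len[2], 1)))
      }
      rid <- sprintf("%s_r%02d", tids[t], r)
      placements[[r]] <- data.frame(read_id = rid, strand = "+",
                                    offset = off[r], aligned_seq = aligned,
                                    stringsAsFactors = FALSE)
      reads[[length(reads) + 1]] <- data.frame(
        read_id = rid, transcript = tids[t], hap = hap[r],
        offset = off[r], len = rl[r], seq = read_seq,
        stringsAsFactors = FALSE)
    }
    if (nr >= 2) {
      contigs[[tids[t]]] <- list(consensus = transcripts[t],
                                 placements = do.call(rbind, placements))
      hv <- hap_variants[[t]]
      if (!is.null(hv)) {
        cov1 <- vapply(hv$pos, function(p)
          sum(hap == 1L & off <= p & p < off + rl), integer(1))
        cov2 <- vapply(hv$pos, function(p)
          sum(hap == 2L & off <= p & p < off + rl), integer(1))
        hv$contig <- tids[t]
        hv$cov_ref <- cov1
        hv$cov_alt <- cov2
        hv$callable <- cov1 >= 2 & cov2 >= 2 & cov1 + cov2 >= 4
        planted_snps[[length(planted_snps) + 1]] <- hv
      }
    } else {
      singleton_rows[[length(singleton_rows) + 1]] <-
        reads[[length(reads)]]
    }
  }
  read_df <- do.call(rbind, reads)
  ests <- est_set(read_df$read_id, read_df$seq, library)
  singles <- if (length(singleton_rows)) {
    sdf <- do.call(rbind, singleton_rows)
    est_set(sdf$read_id, sdf$seq, library)
  } else est_set("placeholder", "ACGT", library)[0, ]
  cs <- cluster_set(contigs, singles, library, n_input = nrow(ests))
  truth <- list(
    planted_ssrs = if (length(planted_ssrs)) do.call(rbind, planted_ssrs)
    else NULL,
    planted_snps = if (length(planted_snps)) do.call(rbind, planted_snps)
    else NULL,
    transcripts = data.frame(seq_id = tids, seq = transcripts,
                             length = tlen, n_reads = n_reads_t,
                             has_ssr = with_ssr, stringsAsFactors = FALSE),
    reads = read_df[, c("read_id", "transcript", "hap", "offset", "len")],
    params = list(n_transcripts = n_transcripts, read_lambda = read_lambda,
                  gc = gc, error_rate = error_rate, ssr = ssr, snp = snp,
                  polya_fraction = polya_fraction, seed = seed))
  list(ests = ests, clusters = cs, truth = truth)
}

#' Simulate a coding-sequence set with controlled GC3
#'
#' Third codon positions are drawn Bernoulli(`gc3_target`) for G/C versus
#' A/T (G vs C and A vs T equiprobable); first and second positions use
#' fixed distinct rates so GC1 and GC2 differ detectably from GC3.
#'
#' @param n_genes number of genes.
#' @param codons_per_gene codons per gene.
#' @param gc3_targets target GC3 per gene, recycled over genes.
#' @param gc12 G+C rates for codon positions 1 and 2.
#' @param seed RNG seed.
#' @return list with `cds` (data.frame seq_id, seq) and `truth`
#'   (seq_id, gc3_target).
#' @export
make_cds_set <- function(n_genes = 200, codons_per_gene = 300,
                         gc3_targets = 0.5, gc12 = c(0.48, 0.42), seed) {
  if (missing(seed)) stopf("seed is required")
  set.seed(seed)
  targets <- rep_len(gc3_targets, n_genes)
  draw_pos <- function(p, n) {
    gcs <- stats::runif(n) < p
    out <- character(n)
    out[gcs] <- sample(c("G", "C"), sum(gcs), replace = TRUE)
    out[!gcs] <- sample(c("A", "T"), sum(!gcs), replace = TRUE)
    out
  }
  seqs <- vapply(seq_len(n_genes), function(g) {
    p1 <- draw_pos(gc12[1], codons_per_gene)
    p2 <- draw_pos(gc12[2], codons_per_gene)
    p3 <- draw_pos(targets[g], codons_per_gene)
    paste(rbind(p1, p2, p3), collapse = "")
  }, character(1))
  ids <- sprintf("G%04d", seq_len(n_genes))
  list(cds = data.frame(seq_id = ids, seq = seqs, stringsAsFactors = FALSE),
       truth = data.frame(seq_id = ids, gc3_target = targets,
                          stringsAsFactors = FALSE))
}

#' Construct an EST containing a hairpin miRNA precursor
#'
#' Builds `flank5 + mature + loop + star + flank3` where the star arm is the
#' reverse complement of the mature sequence with `stem_mismatches`
#' substitutions at interior, spaced positions (substituted to the same base
#' as the mature position, which can pair with nothing). Flanks are random
#' DNA; the loop is an A-run, which cannot pair into the stem without
#' crossing it.
#'
#' @param mature mature miRNA (RNA or DNA), 20-24 nt.
#' @param stem_mismatches number of planted mature/star mismatches (<= 6).
#' @param loop_len terminal loop length (>= 3 nt).
#' @param flank_len random flank length on each side (nt).
#' @param est_id identifier of the emitted record.
#' @param seed RNG seed.
#' @return list with `est` (one-row EST set) and `truth` (mature interval
#'   on the EST, 0-based half-open; arm; mismatch positions within the
#'   mature, 1-based).
#' @export
make_hairpin_est <- function(mature, stem_mismatches = 0, loop_len = 8,
                             flank_len = 15, est_id = "HAIRPIN1", seed) {
  if (missing(seed)) stopf("seed is required")
  m <- nchar(mature)
  if (m < 20 || m > 24) stopf("mature length must be 20-24 nt")
  if (stem_mismatches > 6) stopf("stem_mismatches must be <= 6")
  if (loop_len < 3) stopf("loop_len must be >= 3")
  set.seed(seed)
  mat_dna <- toupper(rna_to_dna(mature))
  star <- seq_chars(revcomp(mat_dna))
  mm_pos <- integer(0)
  if (stem_mismatches > 0) {
    mm_pos <- unique(round(seq(4, m - 3, length.out = stem_mismatches)))
    while (length(mm_pos) < stem_mismatches) {
      extra <- setdiff(4:(m - 3), mm_pos)
      mm_pos <- sort(c(mm_pos, extra[1]))
    }
    mat_chars <- seq_chars(mat_dna)
    for (p in mm_pos) {
      star[m - p + 1] <- mat_chars[p]   # same base pairs with nothing
    }
  }
  flank5 <- if (flank_len > 0) rand_dna(flank_len, 0.5) else ""
  flank3 <- if (flank_len > 0) rand_dna(flank_len, 0.5) else ""
  seq <- paste0(flank5, mat_dna, strrep("A", loop_len),
                paste(star, collapse = ""), flank3)
  start <- nchar(flank5)
  list(est = est_set(est_id, seq, "SYN"),
       truth = list(mature_start = start, mature_end = start + m,
                    arm = "5p", mismatch_positions = mm_pos,
                    loop_len = loop_len, flank_len = flank_len))
}
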