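# Independent oracles used across the suite. Each is a deliberately naive
# re-derivation (regex scans, brute-force translation, count-only DP,
# closed-form statistics) kept separate from the implementation path.

rand_dna_str <- function(n, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

# regex enumeration of perfect repeat runs (maximal, full copies, primitive
# unit, broken at N) -- the reference for the SSR scanner
regex_ssr_oracle <- function(seq, minrep = c(14, 7, 5, 4, 4, 3)) {
  prim <- function(u) {
    k <- nchar(u)
    for (d in seq_len(k - 1)) {
      if (k %% d == 0 && u == strrep(substr(u, 1, d), k / d)) return(FALSE)
    }
    TRUE
  }
  rows <- list()
  for (k in 1:6) {
    pat <- sprintf("([ACGT]{%d})\\1{%d,}", k, minrep[k] - 1)
    m <- gregexpr(pat, seq, perl = TRUE)[[1]]
    if (m[1] == -1) next
    len <- attr(m, "match.length")
    for (i in seq_along(m)) {
      unit <- substr(seq, m[i], m[i] + k - 1)
      if (!prim(unit)) next
      rows[[length(rows) + 1]] <- data.frame(
        unit = unit, unit_len = k, n_repeats = len[i] %/% k,
        start = m[i] - 1L, end = m[i] - 1L + len[i],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(data.frame(unit = character(0),
                                       unit_len = integer(0),
                                       n_repeats = integer(0),
                                       start = integer(0), end = integer(0)))
  out <- do.call(rbind, rows)
  out[order(out$start, out$unit_len), , drop = FALSE]
}

# brute-force longest stop-free stretch over six frames: translate every
# frame codon by codon and split on stops
brute_orf_len <- function(seq) {
  code <- Biostrings::GENETIC_CODE
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  best <- 0L
  for (s in c(seq, rc)) for (off in 0:2) {
    n_codon <- (nchar(s) - off) %/% 3
    if (n_codon < 1) next
    starts <- off + 1 + 3 * (seq_len(n_codon) - 1)
    aa <- unname(code[substring(s, starts, starts + 2)])
    aa[is.na(aa)] <- "X"
    runs <- rle(aa != "*")
    cand <- runs$lengths[runs$values]
    if (length(cand) && max(cand) > best) best <- max(cand)
  }
  best
}

# count-only Nussinov maximum-pairing DP (min loop 3, Watson-Crick + GU)
nussinov_pair_count <- function(seq, min_loop = 3) {
  ch <- strsplit(chartr("T", "U", toupper(seq)), "")[[1]]
  n <- length(ch)
  ok_pair <- function(a, b) paste0(min(a, b), max(a, b)) %in%
    c("CG", "AU", "GU")
  M <- matrix(0L, n, n)
  if (n > min_loop + 1) {
    for (span in (min_loop + 1):(n - 1)) {
      for (i in seq_len(n - span)) {
        j <- i + span
        best <- M[i, j - 1]
        for (k in i:(j - min_loop - 1)) {
          if (!ok_pair(ch[k], ch[j])) next
          v <- (if (k > i) M[i, k - 1] else 0L) + M[k + 1, j - 1] + 1L
          if (v > best) best <- v
        }
        M[i, j] <- best
      }
    }
  }
  M[1, n]
}

# exhaustive sliding-window Hamming scan over both strands; returns the
# minimum mismatch count (Inf when the EST is shorter than the reference)
sliding_hamming_oracle <- function(est_dna, ref_dna) {
  ham <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  best <- Inf
  m <- nchar(ref_dna)
  for (s in c(est_dna,
              as.character(Biostrings::reverseComplement(
                Biostrings::DNAString(est_dna))))) {
    n <- nchar(s)
    if (n < m) next
    for (o in 1:(n - m + 1)) {
      best <- min(best, ham(substr(s, o, o + m - 1), ref_dna))
    }
  }
  best
}

# textbook 2x2 chi-square: sum (O - E)^2 / E without continuity correction
chi2_2x2_oracle <- function(a, b, c, d) {
  obs <- c(a, b, c, d)
  n <- sum(obs)
  rows <- c(a + c, b + d); cols <- c(a + b, c + d)
  expd <- c(rows[1] * cols[1], rows[2] * cols[1],
            rows[1] * cols[2], rows[2] * cols[2]) / n
  stat <- sum((obs - expd)^2 / expd)
  list(stat = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

# per-position counting oracle for codon composition
codon_gc_oracle <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  nc <- length(ch) %/% 3
  ch <- ch[seq_len(3 * nc)]
  pos <- rep(1:3, nc)
  sapply(1:3, function(k) {
    v <- ch[pos == k & ch != "N"]
    mean(v %in% c("G", "C"))
  })
}

toy_mature <- "UGGAGCUCCCUUCAUUCCAAU"   # 21-nt miR159-like test sequence
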