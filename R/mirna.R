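#' Toy RNA energy engine
#'
#' A deliberately simple, deterministic folding/hybridisation energy model:
#' canonical pairs (and G:U wobble) score a per-pair energy by type, and
#' each stack of adjacent pairs earns a bonus. Folding maximises the number
#' of base pairs (Nussinov-style dynamic programming, minimum hairpin loop
#' of 3 nt) and breaks ties toward lower pair-energy sums; the reported MFE
#' is the pair energies plus stacking bonuses of the realised structure.
#' These are toy thermodynamics: absolute kcal/mol values from full
#' nearest-neighbour folders are not reproduced, but the structural criteria
#' built on top of the engine are engine-agnostic, and any list with the
#' same fields can be dropped in as an adapter to an external folder.
#'
#' @param pair_energy named vector: energies for GC, AU and GU pairs
#'   (kcal/mol, negative).
#' @param stack_bonus additional energy per stacked pair.
#' @param min_loop minimum hairpin loop length (nt).
#' @param wobble count G:U as paired.
#' @return an engine list used by [fold_rna()] and [predict_targets()].
#' @export
toy_engine <- function(pair_energy = c(GC = -3, AU = -2, GU = -1),
                       stack_bonus = -1, min_loop = 3, wobble = TRUE) {
  list(name = "toy", pair_energy = pair_energy, stack_bonus = stack_bonus,
       min_loop = min_loop, wobble = wobble)
}

# TRUE if RNA bases a, b can pair under the engine
can_pair <- function(a, b, engine) {
  key <- paste0(pmin(a, b), pmax(a, b))
  ok <- key %in% c("CG", "AU")
  if (engine$wobble) ok <- ok | key == "GU"
  ok
}

pair_energy_of <- function(a, b, engine) {
  key <- paste0(pmin(a, b), pmax(a, b))
  e <- rep(0, length(key))
  e[key == "CG"] <- engine$pair_energy[["GC"]]
  e[key == "AU"] <- engine$pair_energy[["AU"]]
  if (engine$wobble) e[key == "GU"] <- engine$pair_energy[["GU"]]
  e
}

#' Fold an RNA sequence with the built-in engine
#'
#' Maximises base-pair count by dynamic programming (ties resolved toward
#' lower summed pair energy, then deterministically), then scores the
#' realised structure with pair energies and stacking bonuses.
#'
#' @param seq RNA (or DNA; T is read as U) string.
#' @param engine engine from [toy_engine()].
#' @return list of class `fold_result`: seq, structure (dot-bracket), mfe,
#'   engine name, n_pairs, and `partner` (1-based pairing partner or NA).
#' @export
fold_rna <- function(seq, engine = toy_engine()) {
  s <- seq_chars(toupper(dna_to_rna(seq)))
  if (any(!s %in% c("A", "C", "G", "U", "N"))) stopf("invalid residue")
  n <- length(s)
  ml <- engine$min_loop
  sb <- engine$stack_bonus
  NEG <- -.Machine$integer.max %/% 2L
  # three-state lexicographic DP (maximise pairs, then minimise energy):
  #   V: best over structures of [i,j] with i,j paired together
  #   U: best with i,j NOT paired together
  #   W: best overall = lexmax(U, V)
  # energies include stacking bonuses, so among equal pair counts the
  # contiguous helix wins; the pair count of W(1,n) is the Nussinov maximum
  Vp <- matrix(NEG, n, n); Ve <- matrix(Inf, n, n)
  Up <- matrix(0L, n, n); Ue <- matrix(0, n, n)
  Wp <- matrix(0L, n, n); We <- matrix(0, n, n)
  lex_ge <- function(p1, e1, p2, e2) p1 > p2 | (p1 == p2 & e1 <= e2 + 1e-9)
  if (n > ml + 1) {
    for (span in (ml + 1):(n - 1)) {
      for (i in seq_len(n - span)) {
        j <- i + span
        # V: i pairs j
        if (can_pair(s[i], s[j], engine)) {
          e_ij <- pair_energy_of(s[i], s[j], engine)
          ip <- i + 1L; jm <- j - 1L
          inner_p <- 0L; inner_e <- 0
          if (jm - ip > ml) { inner_p <- Up[ip, jm]; inner_e <- Ue[ip, jm] }
          if (jm - ip > ml && Vp[ip, jm] > NEG &&
              !lex_ge(inner_p, inner_e, Vp[ip, jm], Ve[ip, jm] + sb)) {
            inner_p <- Vp[ip, jm]; inner_e <- Ve[ip, jm] + sb
          }
          Vp[i, j] <- inner_p + 1L
          Ve[i, j] <- inner_e + e_ij
        }
        # U: j unpaired, or j pairs some k > i
        bp <- Wp[i, j - 1]; be <- We[i, j - 1]
        ks <- if (i + 1 <= j - ml - 1) (i + 1):(j - ml - 1) else integer(0)
        if (length(ks))
          ks <- ks[can_pair(s[ks], rep(s[j], length(ks)), engine) &
                     Vp[cbind(ks, j)] > NEG]
        if (length(ks)) {
          cp <- Wp[cbind(i, ks - 1)] + Vp[cbind(ks, j)]
          ce <- We[cbind(i, ks - 1)] + Ve[cbind(ks, j)]
          better <- cp > bp | (cp == bp & ce < be - 1e-9)
          if (any(better)) {
            pick <- which(better & cp == max(cp[better]))
            pick <- pick[ce[pick] == min(ce[pick])][1]
            bp <- cp[pick]; be <- ce[pick]
          }
        }
        Up[i, j] <- bp; Ue[i, j] <- be
        # W
        if (Vp[i, j] > NEG &&
            !lex_ge(Up[i, j], Ue[i, j], Vp[i, j], Ve[i, j])) {
          Wp[i, j] <- Vp[i, j]; We[i, j] <- Ve[i, j]
        } else {
          Wp[i, j] <- Up[i, j]; We[i, j] <- Ue[i, j]
        }
      }
    }
  }
  partner <- rep(NA_integer_, n)
  stack <- list(c(1L, n, 0L))   # state 0 = W, 1 = V, 2 = U
  while (length(stack)) {
    su <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    i <- su[1]; j <- su[2]; st <- su[3]
    if (j - i <= ml) next
    if (st == 0L) {  # W: prefer the paired expansion when it attains W
      if (Vp[i, j] > NEG && Vp[i, j] == Wp[i, j] &&
          abs(Ve[i, j] - We[i, j]) < 1e-9) {
        stack[[length(stack) + 1]] <- c(i, j, 1L)
      } else {
        stack[[length(stack) + 1]] <- c(i, j, 2L)
      }
    } else if (st == 1L) {  # V: i pairs j
      partner[i] <- j; partner[j] <- i
      ip <- i + 1L; jm <- j - 1L
      if (jm - ip > ml) {
        e_ij <- pair_energy_of(s[i], s[j], engine)
        if (Vp[ip, jm] > NEG &&
            Vp[i, j] == Vp[ip, jm] + 1L &&
            abs(Ve[i, j] - (Ve[ip, jm] + sb + e_ij)) < 1e-9) {
          stack[[length(stack) + 1]] <- c(ip, jm, 1L)
        } else {
          stack[[length(stack) + 1]] <- c(ip, jm, 2L)
        }
      }
    } else {  # U: smallest attaining k, else j unpaired
      done <- FALSE
      kr <- if (i + 1 <= j - ml - 1) (i + 1):(j - ml - 1) else integer(0)
      for (k in kr) {
        if (!can_pair(s[k], s[j], engine) || Vp[k, j] <= NEG) next
        if (Wp[i, k - 1] + Vp[k, j] == Up[i, j] &&
            abs(We[i, k - 1] + Ve[k, j] - Ue[i, j]) < 1e-9) {
          stack[[length(stack) + 1]] <- c(i, k - 1L, 0L)
          stack[[length(stack) + 1]] <- c(k, j, 1L)
          done <- TRUE
          break
        }
      }
      if (!done) stack[[length(stack) + 1]] <- c(i, j - 1L, 0L)
    }
  }
  paired <- which(!is.na(partner) & partner > seq_len(n))
  structure_chr <- rep(".", n)
  structure_chr[paired] <- "("
  structure_chr[partner[paired]] <- ")"
  structure(list(seq = paste(s, collapse = ""),
                 structure = paste(structure_chr, collapse = ""),
                 mfe = We[1, n], engine = engine$name,
                 n_pairs = Wp[1, n], partner = partner),
            class = "fold_result")
}

#' @export
print.fold_result <- function(x, ...) {
  cat(x$seq, "\n", x$structure, "\n",
      sprintf("%d pairs, MFE %.2f (%s engine)\n", x$n_pairs, x$mfe, x$engine),
      sep = "")
  invisible(x)
}

#' Minimal free energy index (MFEI)
#'
#' `MFEI = (MFE / length * 100) / GC%`, the length- and composition-
#' normalised folding energy used to separate miRNA precursors from other
#' noncoding RNAs (precursors fold unusually tightly for their GC content).
#'
#' @param mfe folding energy (kcal/mol, <= 0).
#' @param length_nt sequence length.
#' @param gc_fraction G+C fraction in (0, 1].
#' @return MFEI (dimensionless, negative).
#' @export
mfei <- function(mfe, length_nt, gc_fraction) {
  if (gc_fraction <= 0) stopf("GC fraction must be positive")
  (mfe / length_nt * 100) / (gc_fraction * 100)
}

# Hamming mismatch profile of `pat` against every window of `txt`
# (both character vectors); returns integer vector over window starts
sliding_mismatches <- function(txt, pat) {
  n <- length(txt); m <- length(pat)
  if (n < m) return(integer(0))
  mm <- integer(n - m + 1)
  for (j in seq_len(m)) {
    mm <- mm + (txt[j:(n - m + j)] != pat[j])
  }
  mm
}

#' Homology screen of ESTs against mature miRNAs
#'
#' Slides each reference mature miRNA over both strands of every EST and
#' keeps the best ungapped window per (EST, reference) pair -- fewest
#' Hamming mismatches, forward strand preferred, then leftmost -- when it
#' has at most `max_mismatch` mismatches (default 3, i.e. fewer than four).
#' T and U are equivalent. Window coordinates are 0-based half-open on the
#' EST's forward strand.
#'
#' @param ests EST set data.frame.
#' @param refs mature miRNA data.frame (see [read_mirna_fasta()]).
#' @param max_mismatch maximum Hamming mismatches retained.
#' @param both_strands screen the reverse complement too.
#' @return data.frame: est_id, ref_id, strand, start, end, mismatches.
#' @export
homology_screen <- function(ests, refs, max_mismatch = 3,
                            both_strands = TRUE) {
  out <- list()
  ref_chars <- lapply(rna_to_dna(refs$seq), seq_chars)
  for (i in seq_len(nrow(ests))) {
    fw <- seq_chars(ests$seq[i])
    rv <- if (both_strands) seq_chars(revcomp(ests$seq[i])) else NULL
    n <- length(fw)
    for (r in seq_along(ref_chars)) {
      pat <- ref_chars[[r]]
      m <- length(pat)
      best <- NULL
      mmf <- sliding_mismatches(fw, pat)
      if (length(mmf) && min(mmf) <= max_mismatch) {
        w <- which.min(mmf)
        best <- list(strand = "+", start = w - 1L, mm = mmf[w])
      }
      if (!is.null(rv)) {
        mmr <- sliding_mismatches(rv, pat)
        if (length(mmr) && min(mmr) <= max_mismatch &&
            (is.null(best) || min(mmr) < best$mm)) {
          w <- which.min(mmr)
          # window on rc maps to forward coords [n - w + 1 - m, n - w + 1)
          best <- list(strand = "-", start = n - (w - 1L) - m, mm = mmr[w])
        }
      }
      if (!is.null(best)) {
        out[[length(out) + 1]] <- data.frame(
          est_id = ests$id[i], ref_id = refs$id[r], strand = best$strand,
          start = best$start, end = best$start + m,
          mismatches = best$mm, stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame(est_id = character(0),
                                      ref_id = character(0),
                                      strand = character(0),
                                      start = integer(0), end = integer(0),
                                      mismatches = integer(0),
                                      stringsAsFactors = FALSE)
  res
}

#' Precursor filter thresholds
#'
#' Defaults implement the five classic homology-screening criteria for
#' plant pre-miRNA candidates: a hairpin with the mature sequence in one
#' arm; MFE at most `mfe_max` and |MFEI| at least `mfei_min`; mature A+U
#' content within `au_range`; fewer than `max_star_mismatch` mature
#' positions unpaired against the star arm; and no bulge or loop longer
#' than `max_bulge` inside the duplex.
#'
#' @param mfe_max maximum (most positive) acceptable MFE, kcal/mol.
#' @param mfei_min minimum |MFEI|.
#' @param au_range inclusive mature A+U content window.
#' @param max_star_mismatch mature/star mismatches must be strictly below.
#' @param max_bulge largest tolerated bulge/loop inside the duplex (nt).
#' @return list of thresholds for [evaluate_precursor()].
#' @export
precursor_thresholds <- function(mfe_max = -25, mfei_min = 0.85,
                                 au_range = c(0.30, 0.70),
                                 max_star_mismatch = 6, max_bulge = 3) {
  list(mfe_max = mfe_max, mfei_min = mfei_min, au_range = au_range,
       max_star_mismatch = max_star_mismatch, max_bulge = max_bulge)
}

#' Evaluate a screened EST window as a miRNA precursor candidate
#'
#' Folds the mature-match window padded by `window_pad` nt on each side
#' (truncated at the EST ends) and records the five filter criteria: (1)
#' hairpin with the mature sequence inside one arm, (2) MFE and MFEI
#' thresholds, (3) mature A+U content 30-70%, (4) fewer than six
#' mature/star mismatches, (5) no bulge or loop over 3 nt inside the
#' duplex. Mature/star correspondence is anchored on the realised pairing:
#' the dominant-arm partners define the star register (median of position +
#' partner), and a mature position counts as mismatched when it cannot pair
#' with its registered star counterpart. This keeps the mismatch count
#' robust to incidental pairings outside the stem.
#'
#' @param est_seq the EST sequence (DNA).
#' @param start,end mature match window, 0-based half-open on the forward
#'   strand.
#' @param est_id,ref_id identifiers carried through.
#' @param window_pad nt of context folded on each side of the window.
#' @param engine energy engine.
#' @param thresholds from [precursor_thresholds()].
#' @return list: ids, window, fold, mfe, mfei, au_content,
#'   duplex_mismatches, max_duplex_gap, arm, passed (named logical vector
#'   crit1..crit5) and `all_passed`.
#' @export
evaluate_precursor <- function(est_seq, start, end, est_id = NA, ref_id = NA,
                               window_pad = 40, engine = toy_engine(),
                               thresholds = precursor_thresholds()) {
  n <- nchar(est_seq)
  ws <- max(0L, start - window_pad)
  we <- min(n, end + window_pad)
  window <- substr(est_seq, ws + 1, we)
  fold <- fold_rna(window, engine)
  wlen <- we - ws
  mat_rel <- (start - ws + 1):(end - ws)        # 1-based within window
  s <- seq_chars(fold$seq)
  partner <- fold$partner
  mp <- partner[mat_rel]
  paired <- !is.na(mp)
  ext <- paired & (mp < min(mat_rel) | mp > max(mat_rel))
  n_up <- sum(ext & mp > max(mat_rel))
  n_dn <- sum(ext & mp < min(mat_rel))
  arm <- if (n_up >= n_dn) "5p" else "3p"
  # mature/star mismatches are an ungapped duplex comparison against the
  # opposite arm: the fold decides which side the star arm is on, and the
  # register (constant position + counterpart sum of an antiparallel stem)
  # is the one maximising complementary correspondences on that side. This
  # keeps the count robust to incidental pairings the count-maximising
  # fold may add elsewhere.
  regions <- list(
    `5p` = if (max(mat_rel) < wlen) (max(mat_rel) + 1):wlen else integer(0),
    `3p` = if (min(mat_rel) > 1) 1:(min(mat_rel) - 1) else integer(0))
  best_match <- -1L; match_ok <- rep(FALSE, length(mat_rel))
  best_side <- arm
  for (side in names(regions)) {
    region <- regions[[side]]
    if (!length(region)) next
    for (reg in (min(region) + min(mat_rel)):(max(region) + max(mat_rel))) {
      q <- reg - mat_rel
      valid <- q %in% region
      ok <- rep(FALSE, length(mat_rel))
      if (any(valid))
        ok[valid] <- can_pair(s[mat_rel[valid]], s[q[valid]], engine)
      if (sum(ok) > best_match ||
          (sum(ok) == best_match && side == arm && best_side != arm)) {
        best_match <- sum(ok); match_ok <- ok; best_side <- side
      }
    }
  }
  arm <- best_side
  # in one arm: external pairs agree on a side and at least half the mature
  # positions find counterparts in the opposing arm (a window spanning the
  # terminal loop loses its counterparts into the window itself)
  crit1 <- sum(ext) > 0 && max(n_up, n_dn) > sum(ext) / 2 &&
    best_match >= ceiling(length(mat_rel) / 2)
  duplex_mismatches <- sum(!match_ok)
  mm_runs <- rle(!match_ok)
  max_gap <- if (any(!match_ok)) max(mm_runs$lengths[mm_runs$values]) else 0L
  mature_seq <- s[mat_rel]
  au <- mean(mature_seq %in% c("A", "U"))
  fold_mfei <- mfei(fold$mfe, wlen, gc_fraction(window))
  passed <- c(
    crit1 = crit1,
    crit2 = fold$mfe <= thresholds$mfe_max &&
      abs(fold_mfei) >= thresholds$mfei_min,
    crit3 = au >= thresholds$au_range[1] & au <= thresholds$au_range[2],
    crit4 = duplex_mismatches < thresholds$max_star_mismatch,
    crit5 = max_gap <= thresholds$max_bulge)
  list(est_id = est_id, ref_id = ref_id,
       window_start = ws, window_end = we,
       mature_start = start, mature_end = end,
       fold = fold, mfe = fold$mfe, mfei = fold_mfei, au_content = au,
       duplex_mismatches = duplex_mismatches, max_duplex_gap = max_gap,
       arm = arm, passed = passed, all_passed = all(passed))
}

# duplex statistics for one ungapped offset: mature vs reversed window
duplex_stats <- function(paired_vec, energies, stack_bonus) {
  m <- length(paired_vec)
  e <- sum(energies[paired_vec]) +
    stack_bonus * sum(paired_vec[-m] & paired_vec[-1])
  r <- rle(paired_vec)
  helix_len <- if (any(r$values)) max(r$lengths[r$values]) else 0L
  interior <- which(paired_vec)
  loops <- 0L
  if (length(interior) > 1) {
    inner <- r
    # interior unpaired runs only
    first_t <- which(r$values)[1]; last_t <- rev(which(r$values))[1]
    runs <- r$lengths[!r$values &
                        seq_along(r$values) > first_t &
                        seq_along(r$values) < last_t]
    loops <- if (length(runs)) max(runs) else 0L
  }
  ov5 <- if (paired_vec[1]) 0L else r$lengths[1]
  ovm <- if (paired_vec[m]) 0L else r$lengths[length(r$lengths)]
  list(energy = e, helix_len = helix_len, max_internal_loop = loops,
       overhang_5p = ov5, overhang_3p = ovm)
}

#' Predict miRNA target sites in ESTs
#'
#' Hybridises the mature miRNA against every same-length window of each EST
#' (ungapped antiparallel duplex under the engine's pair and stacking
#' energies; bulges are therefore 0 by construction) and keeps the best
#' site. A site is accepted when its energy is at or below
#' `fraction * perfect_mfe` (the energy of the mature sequence hybridised
#' to its exact reverse complement), both end overhangs are at most 2 nt,
#' no internal loop exceeds 1 nt, and the seed region (mature positions
#' 8-12) is fully paired -- the helix-constraint window of classic target
#' screens.
#'
#' @param mature mature miRNA sequence (RNA or DNA).
#' @param ests EST set data.frame.
#' @param engine energy engine.
#' @param fraction of the perfect-complement MFE required (default 0.7).
#' @param max_overhang maximum unpaired nt at either duplex end.
#' @param max_internal_loop maximum interior unpaired run (nt).
#' @param helix_window mature positions that must be fully paired.
#' @return data.frame with one row per EST: est_id, start, mfe,
#'   perfect_mfe, threshold, overhang_5p, overhang_3p, helix_len,
#'   max_internal_loop, max_bulge, seed_paired, accepted.
#' @export
predict_targets <- function(mature, ests, engine = toy_engine(),
                            fraction = 0.7, max_overhang = 2,
                            max_internal_loop = 1, helix_window = c(8, 12)) {
  mat <- seq_chars(toupper(dna_to_rna(mature)))
  m <- length(mat)
  perfect <- sum(pair_energy_of(mat, chartr("AUGC", "UACG", mat), engine)) +
    engine$stack_bonus * (m - 1)
  threshold <- fraction * perfect
  rows <- list()
  for (i in seq_len(nrow(ests))) {
    w <- seq_chars(dna_to_rna(ests$seq[i]))
    n <- length(w)
    if (n < m) next
    noff <- n - m + 1
    paired <- matrix(FALSE, m, noff)
    energies <- matrix(0, m, noff)
    for (k in seq_len(m)) {
      # mature position k pairs with window position m - k + 1,
      # i.e. EST position o + m - k for window start o
      tgt <- w[(m - k + 1):(n - k + 1)]
      paired[k, ] <- can_pair(rep(mat[k], noff), tgt, engine)
      energies[k, ] <- ifelse(paired[k, ],
                              pair_energy_of(rep(mat[k], noff), tgt, engine),
                              0)
    }
    best <- NULL
    for (o in seq_len(noff)) {
      st <- duplex_stats(paired[, o], stats::setNames(energies[, o], NULL),
                         engine$stack_bonus)
      st$energy <- sum(energies[, o][paired[, o]]) +
        engine$stack_bonus * sum(paired[-m, o] & paired[-1, o])
      seed_ok <- all(paired[helix_window[1]:helix_window[2], o])
      acc <- st$energy <= threshold && st$overhang_5p <= max_overhang &&
        st$overhang_3p <= max_overhang &&
        st$max_internal_loop <= max_internal_loop && seed_ok
      cand <- list(start = o - 1L, stats = st, seed = seed_ok, accepted = acc)
      if (is.null(best) ||
          (cand$accepted && !best$accepted) ||
          (cand$accepted == best$accepted &&
           cand$stats$energy < best$stats$energy)) best <- cand
    }
    if (is.null(best)) next
    rows[[length(rows) + 1]] <- data.frame(
      est_id = ests$id[i], start = best$start,
      mfe = best$stats$energy, perfect_mfe = perfect, threshold = threshold,
      overhang_5p = best$stats$overhang_5p,
      overhang_3p = best$stats$overhang_3p,
      helix_len = best$stats$helix_len,
      max_internal_loop = best$stats$max_internal_loop,
      max_bulge = 0L, seed_paired = best$seed, accepted = best$accepted,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  if (is.null(res)) res <- data.frame(
    est_id = character(0), start = integer(0), mfe = numeric(0),
    perfect_mfe = numeric(0), threshold = numeric(0),
    overhang_5p = integer(0), overhang_3p = integer(0),
    helix_len = integer(0), max_internal_loop = integer(0),
    max_bulge = integer(0), seed_paired = logical(0), accepted = logical(0),
    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Acceptance threshold for target sites
#'
#' The classic 70%-of-perfect rule: a candidate duplex must reach at least
#' `fraction` of the energy of the mature sequence hybridised to its exact
#' complement.
#'
#' @param perfect_mfe perfect-complement duplex energy (kcal/mol).
#' @param fraction required fraction (default 0.7).
#' @return the acceptance threshold in kcal/mol.
#' @export
target_mfe_threshold <- function(perfect_mfe, fraction = 0.7) {
  fraction * perfect_mfe
}

#' Write precursor candidates as TSV
#'
#' @param cands list of results from [evaluate_precursor()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_candidate_tsv <- function(cands, path) {
  df <- do.call(rbind, lapply(cands, function(x) data.frame(
    est_id = x$est_id, ref_id = x$ref_id,
    mature_start = x$mature_start + 1L, mature_end = x$mature_end,
    mfe = x$mfe, mfei = x$mfei, au = x$au_content,
    duplex_mismatches = x$duplex_mismatches, arm = x$arm,
    criteria = paste(ifelse(x$passed, "1", "0"), collapse = ""),
    all_passed = x$all_passed, structure = x$fold$structure,
    stringsAsFactors = FALSE)))
  if (is.null(df)) df <- data.frame(est_id = character(0))
  write_tsv(df, path)
}
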