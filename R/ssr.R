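#' Detect perfect microsatellites (SSRs)
#'
#' Scans each sequence for maximal runs of a tandemly repeated 1-6 nt unit.
#' A run is reported when its number of complete unit copies reaches the
#' class threshold; defaults are the classic EST-SSR settings of seven
#' copies for dinucleotides, five for tri-, four for tetra- and penta-, and
#' three for hexanucleotide units, with mononucleotide runs requiring
#' `min_mono_len` (14) nt. Units are primitive (a run of `ATAT` units is
#' reported once as an `AT` dinucleotide run, never again with a
#' longer period), runs are broken at N, and intervals cover complete unit
#' copies only, left-aligned. Coordinates are 0-based half-open internally;
#' report writers emit 1-based inclusive.
#'
#' @param ests EST set data.frame (or any data.frame with id and seq).
#' @param thresholds named vector mapping unit length ("2".."6") to the
#'   minimum number of repeats.
#' @param min_mono_len minimum mononucleotide run length in nt.
#' @return data.frame with seq_id, unit, unit_len, n_repeats, start, end
#'   (0-based half-open) and canonical_unit (lexicographically minimal
#'   rotation), sorted by seq_id then start.
#' @export
find_perfect_ssrs <- function(ests,
                              thresholds = c(`2` = 7, `3` = 5, `4` = 4,
                                             `5` = 4, `6` = 3),
                              min_mono_len = 14) {
  minrep <- c(min_mono_len, thresholds[as.character(2:6)])
  out <- lapply(seq_len(nrow(ests)), function(i) {
    h <- scan_ssr_seq(ests$seq[i], minrep)
    if (!nrow(h)) return(NULL)
    h$seq_id <- ests$id[i]
    h
  })
  res <- do.call(rbind, out)
  if (is.null(res) || !nrow(res)) return(empty_ssr_df())
  res <- res[order(res$seq_id, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res[, c("seq_id", "unit", "unit_len", "n_repeats", "start", "end",
          "canonical_unit")]
}

empty_ssr_df <- function() {
  data.frame(seq_id = character(0), unit = character(0),
             unit_len = integer(0), n_repeats = integer(0),
             start = integer(0), end = integer(0),
             canonical_unit = character(0), stringsAsFactors = FALSE)
}

# core scanner for one sequence: compares the sequence against itself shifted
# by the unit length; maximal TRUE runs of that comparison are periodic
# regions, trimmed to complete unit copies (left-aligned).
scan_ssr_seq <- function(seq, minrep) {
  ch <- seq_chars(seq)
  n <- length(ch)
  rows <- list()
  for (k in 1:6) {
    if (n < k * minrep[k]) next
    lead <- ch[seq_len(n - k)]
    lag <- ch[(k + 1):n]
    ok <- lead == lag & lead != "N" & lag != "N"
    r <- rle(ok)
    starts <- cumsum(c(1L, r$lengths))[seq_along(r$lengths)]
    for (j in which(r$values)) {
      i <- starts[j]
      nrep <- (r$lengths[j] + k) %/% k
      if (nrep < minrep[k]) next
      unit <- substr(seq, i, i + k - 1)
      if (!is_primitive_unit(unit)) next
      rows[[length(rows) + 1]] <- data.frame(
        unit = unit, unit_len = k, n_repeats = nrep,
        start = i - 1L, end = i - 1L + nrep * k,
        canonical_unit = canonical_rotation(unit),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    out <- empty_ssr_df()
    out$seq_id <- NULL
    return(out)
  }
  do.call(rbind, rows)
}

# TRUE unless the unit is itself a repetition of a shorter unit
is_primitive_unit <- function(unit) {
  k <- nchar(unit)
  for (d in seq_len(k - 1)) {
    if (k %% d == 0 &&
        unit == strrep(substr(unit, 1, d), k / d)) return(FALSE)
  }
  TRUE
}

#' Lexicographically minimal rotation of a repeat unit
#'
#' Canonical motif labels are rotation-invariant (`TA` and `AT` runs are the
#' same motif class) but reverse complements are kept distinct, matching how
#' di-/trinucleotide repeat types are tabulated in EST surveys.
#'
#' @param unit repeat unit string(s).
#' @return canonical rotation(s).
#' @export
canonical_rotation <- function(unit) {
  vapply(unit, function(u) {
    k <- nchar(u)
    rot <- vapply(0:(k - 1), function(r)
      paste0(substr(u, r + 1, k), substr(u, 1, r)), character(1))
    min(rot)
  }, character(1), USE.NAMES = FALSE)
}

#' Drop mononucleotide poly-A / poly-T runs
#'
#' A and T homopolymers are overwhelmingly 3' mRNA tail remnants in cDNA
#' data and are excluded from SSR tallies; all other hits (including AT
#' dinucleotide repeats and C/G homopolymers) pass unchanged.
#'
#' @param hits SSR hit data.frame from [find_perfect_ssrs()].
#' @return filtered hit data.frame.
#' @export
exclude_polyAT <- function(hits) {
  drop <- hits$unit_len == 1 & hits$unit %in% c("A", "T")
  out <- hits[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Resolve overlapping SSR hits
#'
#' Rarely, maximal runs of different periods overlap by a few bases (e.g. a
#' homopolymer run abutting a dinucleotide run sharing its edge base).
#' Downstream compound merging requires disjoint hits, so overlaps are
#' resolved greedily: longer intervals win, ties go to the earlier start and
#' then the shorter unit.
#'
#' @param hits SSR hit data.frame.
#' @return hit data.frame with overlaps removed, sorted by seq_id and start.
#' @export
resolve_ssr_overlaps <- function(hits) {
  if (!nrow(hits)) return(hits)
  keep <- unlist(lapply(split(seq_len(nrow(hits)), hits$seq_id), function(idx) {
    h <- hits[idx, , drop = FALSE]
    ord <- order(-(h$end - h$start), h$start, h$unit_len)
    taken <- logical(length(idx))
    occupied <- integer(0)
    for (r in ord) {
      span <- (h$start[r] + 1):h$end[r]
      if (!any(span %in% occupied)) {
        taken[r] <- TRUE
        occupied <- c(occupied, span)
      }
    }
    idx[taken]
  }), use.names = FALSE)
  out <- hits[sort(keep), , drop = FALSE]
  out <- out[order(out$seq_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Chain nearby SSRs into compound microsatellites
#'
#' Two repeats separated by a non-repetitive stretch of at most `max_gap`
#' (default 100) nucleotides belong to the same compound microsatellite;
#' chaining is transitive, so compounds are the connected components of the
#' gap-threshold interval graph. Isolated hits are flagged `simple`.
#' Members may have different unit lengths; membership is purely gap-based.
#'
#' @param hits SSR hit data.frame (non-overlapping; see
#'   [resolve_ssr_overlaps()]).
#' @param max_gap maximum non-repetitive stretch between members (nt).
#' @return list with `members` (hits plus compound_id) and `compounds`
#'   (one row per chain: compound_id, seq_id, n_members, start, end, type).
#' @export
merge_compound <- function(hits, max_gap = 100) {
  if (!nrow(hits)) {
    return(list(members = cbind(hits, compound_id = character(0)),
                compounds = data.frame(compound_id = character(0),
                                       seq_id = character(0),
                                       n_members = integer(0),
                                       start = integer(0), end = integer(0),
                                       type = character(0),
                                       stringsAsFactors = FALSE)))
  }
  hits <- hits[order(hits$seq_id, hits$start), , drop = FALSE]
  rownames(hits) <- NULL
  cid <- character(nrow(hits))
  counter <- 0L
  for (sid in unique(hits$seq_id)) {
    idx <- which(hits$seq_id == sid)
    h <- hits[idx, , drop = FALSE]
    if (nrow(h) > 1) {
      gap <- h$start[-1] - h$end[-nrow(h)]
      if (any(gap < 0)) stopf("overlapping SSR hits on %s; resolve upstream", sid)
      newgrp <- c(TRUE, gap > max_gap)
    } else newgrp <- TRUE
    grp <- cumsum(newgrp)
    for (g in unique(grp)) {
      counter <- counter + 1L
      cid[idx[grp == g]] <- sprintf("cmp%05d", counter)
    }
  }
  members <- cbind(hits, compound_id = cid, stringsAsFactors = FALSE)
  agg <- lapply(split(members, members$compound_id), function(d) {
    data.frame(compound_id = d$compound_id[1], seq_id = d$seq_id[1],
               n_members = nrow(d), start = min(d$start), end = max(d$end),
               type = if (nrow(d) > 1) "compound" else "simple",
               stringsAsFactors = FALSE)
  })
  compounds <- do.call(rbind, agg)
  compounds <- compounds[order(compounds$seq_id, compounds$start), ,
                         drop = FALSE]
  rownames(compounds) <- NULL
  list(members = members, compounds = compounds)
}

#' Repeat-type frequency table
#'
#' Counts SSR hits per unit-length class (mono- to hexanucleotide) and per
#' canonical motif, with percentages of the total.
#'
#' @param hits SSR hit data.frame (poly-A/T already excluded).
#' @return list with `classes` (unit_len, class, n, pct), `total`, and
#'   `motifs` (canonical_unit, unit_len, n).
#' @export
repeat_frequency_table <- function(hits) {
  class_names <- c("mono", "di", "tri", "tetra", "penta", "hexa")
  n <- vapply(1:6, function(k) sum(hits$unit_len == k), integer(1))
  total <- sum(n)
  pct <- if (total > 0) 100 * n / total else rep(0, 6)
  classes <- data.frame(unit_len = 1:6, class = class_names, n = n,
                        pct = pct, stringsAsFactors = FALSE)
  motifs <- if (nrow(hits)) {
    agg <- stats::aggregate(list(n = hits$start),
                            by = list(canonical_unit = hits$canonical_unit,
                                      unit_len = hits$unit_len),
                            FUN = length)
    agg[order(agg$unit_len, -agg$n, agg$canonical_unit), , drop = FALSE]
  } else {
    data.frame(canonical_unit = character(0), unit_len = integer(0),
               n = integer(0), stringsAsFactors = FALSE)
  }
  rownames(motifs) <- NULL
  list(classes = classes, total = total, motifs = motifs)
}

#' SSR density in kilobases per repeat
#'
#' @param total_scanned_bp total bases scanned.
#' @param n_ssrs number of SSRs found (> 0; NA is returned for 0).
#' @return kb of sequence per SSR.
#' @export
ssr_density <- function(total_scanned_bp, n_ssrs) {
  if (n_ssrs <= 0) return(NA_real_)
  (total_scanned_bp / 1000) / n_ssrs
}

#' Write SSR hits as GFF3
#'
#' Features are typed `microsatellite` with unit, canonical unit and repeat
#' number attributes; coordinates are 1-based inclusive per GFF3.
#'
#' @param hits SSR hit data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ssr_gff3 <- function(hits, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(hits)) {
    lines <- sprintf(
      "%s\testminer\tmicrosatellite\t%d\t%d\t.\t+\t.\tunit=%s;canonical_unit=%s;n_repeats=%d",
      hits$seq_id, hits$start + 1L, hits$end, hits$unit,
      hits$canonical_unit, hits$n_repeats)
    writeLines(lines, con)
  }
  invisible(path)
}

#' Write SSR hits as TSV (1-based inclusive coordinates)
#'
#' @param hits SSR hit data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ssr_tsv <- function(hits, path) {
  out <- hits
  out$start <- out$start + 1L
  names(out)[names(out) == "start"] <- "start_1based"
  names(out)[names(out) == "end"] <- "end_1based"
  write_tsv(out, path)
}
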