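test_that("scanner reports threshold boundaries and primitive units", {
  e <- est_set(c("a", "b", "c", "d", "e"),
               c(paste0("G", strrep("AT", 7), "G"),   # exactly at di >= 7
                 paste0("G", strrep("AT", 6), "G"),   # below threshold
                 strrep("C", 14),                     # mono C run kept
                 paste0("TTGG", strrep("ACG", 5), "TT"),
                 paste0("AA", strrep("ACGTG", 4), "CC")))
  hits <- find_perfect_ssrs(e)
  a <- hits[hits$seq_id == "a", ]
  expect_equal(nrow(a), 1)
  expect_equal(a$unit, "AT")
  expect_equal(a$n_repeats, 7)
  expect_equal(c(a$start, a$end), c(1L, 15L))
  expect_false("b" %in% hits$seq_id)
  cc <- hits[hits$seq_id == "c", ]
  expect_equal(cc$unit_len, 1)
  expect_equal(cc$n_repeats, 14)
  # maximal runs may left-extend into a flanking base that matches the
  # unit edge, so the motif is compared rotation-invariantly
  expect_equal(hits$canonical_unit[hits$seq_id == "d"],
               canonical_rotation("ACG"))
  expect_equal(hits$canonical_unit[hits$seq_id == "e"],
               canonical_rotation("ACGTG"))
})

test_that("runs containing N are broken and non-primitive units suppressed", {
  e <- est_set(c("n1", "np"),
               c(paste0(strrep("AG", 7), "N", strrep("AG", 7)),
                 strrep("AT", 14)))                    # 28 nt pure AT
  hits <- find_perfect_ssrs(e)
  n1 <- hits[hits$seq_id == "n1", ]
  expect_equal(nrow(n1), 2)       # both halves, neither spanning the N
  expect_true(all(n1$n_repeats == 7))
  np <- hits[hits$seq_id == "np", ]
  expect_equal(nrow(np), 1)       # reported once, as the primitive AT unit
  expect_equal(np$unit_len, 2)
  expect_equal(np$n_repeats, 14)
})

test_that("scanner equals the regex enumeration oracle on random sequence", {
  set.seed(404)
  for (rep in 1:4) {
    # low-cardinality alphabet stretches make repeats frequent
    seq <- paste0(rand_dna_str(8000),
                  paste(sample(c("A", "T"), 1500, replace = TRUE),
                        collapse = ""),
                  rand_dna_str(8000),
                  paste(sample(c("A", "C"), 1500, replace = TRUE),
                        collapse = ""),
                  rand_dna_str(1000))
    got <- find_perfect_ssrs(est_set("s", seq))
    want <- regex_ssr_oracle(seq)
    got <- got[order(got$start, got$unit_len), ]
    want <- want[order(want$start, want$unit_len), ]
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$unit, want$unit)
    expect_equal(got$n_repeats, want$n_repeats)
  }
})

test_that("canonical rotation is rotation-invariant, reverse complements distinct", {
  expect_equal(canonical_rotation(c("TA", "AT")), c("AT", "AT"))
  expect_equal(canonical_rotation("GAT"), canonical_rotation("ATG"))
  expect_false(canonical_rotation("AG") == canonical_rotation("CT"))
})

test_that("poly-A/T exclusion removes exactly the A and T mononucleotide runs", {
  hits <- data.frame(
    seq_id = "s", unit = c("A", "T", "C", "G", "AT", "AAT"),
    unit_len = c(1, 1, 1, 1, 2, 3), n_repeats = c(20, 15, 14, 14, 8, 6),
    start = c(0, 30, 60, 90, 120, 150),
    end = c(20, 45, 74, 104, 136, 168),
    canonical_unit = c("A", "T", "C", "G", "AT", "AAT"),
    stringsAsFactors = FALSE)
  kept <- exclude_polyAT(hits)
  # filter oracle: everything except mononucleotide A/T
  want <- hits[!(hits$unit_len == 1 & hits$unit %in% c("A", "T")), ]
  expect_equal(kept$unit, want$unit)
  expect_true(all(c("C", "G", "AT", "AAT") %in% kept$unit))
})

test_that("compound chaining equals connected components of the gap graph", {
  h <- function(starts, ends) data.frame(
    seq_id = "s", unit = "AT", unit_len = 2,
    n_repeats = (ends - starts) / 2, start = starts, end = ends,
    canonical_unit = "AT", stringsAsFactors = FALSE)
  two <- merge_compound(h(c(0, 50), c(14, 65)))
  expect_equal(two$compounds$n_members, 2)
  expect_equal(two$compounds$type, "compound")

  apart <- merge_compound(h(c(0, 115), c(14, 130)))   # gap 101
  expect_equal(apart$compounds$n_members, c(1, 1))
  expect_equal(apart$compounds$type, c("simple", "simple"))

  at_gap <- merge_compound(h(c(0, 114), c(14, 129)))  # gap exactly 100
  expect_equal(at_gap$compounds$n_members, 2)

  expect_error(merge_compound(h(c(0, 10), c(14, 24))), "overlapping")

  # random hit sets vs a graph-component oracle
  set.seed(77)
  for (rep in 1:20) {
    k <- sample(2:12, 1)
    starts <- sort(sample(seq(0, 4000, by = 2), k))
    ends <- starts + 14
    keep <- c(TRUE, diff(starts) > 14)   # drop overlaps
    starts <- starts[keep]; ends <- ends[keep]
    res <- merge_compound(h(starts, ends))
    # oracle: components via adjacency of consecutive gaps
    grp <- cumsum(c(TRUE, (starts[-1] - ends[-length(ends)]) > 100))
    expect_equal(unname(table(factor(grp))[as.character(seq_len(max(grp)))]),
                 res$compounds$n_members[order(res$compounds$start)],
                 ignore_attr = TRUE)
  }
})

test_that("frequency table percentages match a hand recount and sum to 100", {
  hits <- data.frame(
    unit_len = rep(1:6, c(3, 229, 101, 18, 4, 52)),
    unit = "x", canonical_unit = "x", seq_id = "s",
    n_repeats = 7, start = 0, end = 14, stringsAsFactors = FALSE)
  ft <- repeat_frequency_table(hits)
  expect_equal(ft$total, 407)
  expect_equal(ft$classes$n, c(3, 229, 101, 18, 4, 52))
  expect_equal(ft$classes$pct, 100 * c(3, 229, 101, 18, 4, 52) / 407)
  expect_equal(sum(ft$classes$pct), 100, tolerance = 1e-9)
  one <- repeat_frequency_table(hits[1, , drop = FALSE])
  expect_equal(one$classes$pct[1], 100)
  zero <- repeat_frequency_table(hits[0, , drop = FALSE])
  expect_equal(zero$total, 0)
  expect_true(all(zero$classes$n == 0))
})

test_that("SSR density follows kb-per-repeat arithmetic", {
  expect_equal(ssr_density(1188440, 407), 1188440 / 1000 / 407)
  expect_equal(ssr_density(1000, 1), 1)
  expect_true(is.na(ssr_density(1000, 0)))
})

test_that("planted SSRs are recovered exactly and clean regions stay empty", {
  lib <- make_est_library(n_transcripts = 80, read_lambda = 0.5,
                          transcript_len = c(400, 60),
                          ssr = ssr_spec(fraction = 0.4),
                          snp = snp_spec(p_snp = 0), seed = 55)
  tx <- est_set(lib$truth$transcripts$seq_id, lib$truth$transcripts$seq)
  hits <- exclude_polyAT(find_perfect_ssrs(tx))
  truth <- lib$truth$planted_ssrs
  expect_equal(nrow(hits), nrow(truth))
  m <- merge(truth, hits, by = "seq_id")
  expect_equal(nrow(m), nrow(truth))
  expect_equal(m$start.x, m$start.y)
  expect_equal(m$end.x, m$end.y)
  expect_equal(m$n_repeats.x, m$n_repeats.y)
  # no hit on any transcript certified repeat-free
  clean <- lib$truth$transcripts$seq_id[!lib$truth$transcripts$has_ssr]
  expect_false(any(hits$seq_id %in% clean))
})

test_that("GFF3 output is 1-based inclusive with microsatellite features", {
  hits <- find_perfect_ssrs(est_set("s1", paste0("G", strrep("AT", 7), "G")))
  path <- withr::local_tempfile(fileext = ".gff3")
  write_ssr_gff3(hits, path)
  lines <- readLines(path)
  expect_equal(lines[1], "##gff-version 3")
  f <- strsplit(lines[2], "\t")[[1]]
  expect_equal(f[3], "microsatellite")
  expect_equal(as.integer(f[4]), 2L)   # 0-based 1 -> 1-based 2
  expect_equal(as.integer(f[5]), 15L)
})
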