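# build a contig directly from full-length aligned reads
contig_of <- function(...) {
  reads <- c(...)
  list(consensus = gsub("-", "", reads[1], fixed = TRUE),
       placements = data.frame(read_id = sprintf("r%d", seq_along(reads)),
                               strand = "+", offset = 0L,
                               aligned_seq = reads,
                               stringsAsFactors = FALSE))
}

test_that("redundancy rule calls balanced columns and skips singletons", {
  # column 4 (0-based 3): A in three reads, G in three reads -> transition
  base <- "ACGTACGTACGT"
  alt <- "ACGGACGTACGT"
  ct <- contig_of(base, base, base, alt, alt, alt)
  calls <- call_snps(ct, "c1")
  expect_equal(nrow(calls), 1)
  expect_equal(calls$pos, 3L)
  expect_setequal(c(calls$allele1, calls$allele2), c("T", "G"))
  expect_equal(calls$kind, "substitution")
  expect_equal(calls$subst_class, "transversion")  # T vs G
  expect_equal(calls$redundancy, 3L)

  # {A,G} column is a transition
  ts <- call_snps(contig_of("AAAAAAAA", "AAAAAAAA", "AAGAAAAA",
                            "AAGAAAAA"), "c2")
  expect_equal(ts$subst_class, "transition")

  # a singleton allele (1 read) is treated as sequencing error
  err <- call_snps(contig_of(base, base, base, base, base, alt), "c3")
  expect_equal(nrow(err), 0)
})

test_that("gap alleles are indel events, adjacent gap columns collapse", {
  with_gap <- "ACG--CGTACGT"
  full <- "ACGTACGTACGT"
  ct <- list(consensus = full,
             placements = data.frame(
               read_id = sprintf("r%d", 1:4), strand = "+", offset = 0L,
               aligned_seq = c(full, full, with_gap, with_gap),
               stringsAsFactors = FALSE))
  calls <- call_snps(ct, "c1")
  expect_equal(sum(calls$kind == "indel"), 1)   # one event, not two columns
  expect_equal(calls$pos[calls$kind == "indel"], 3L)
  expect_equal(calls$subst_class[calls$kind == "indel"], "none")
})

test_that("co-segregation scores reflect haplotype consistency", {
  # two perfectly linked SNPs on six reads
  hapA <- "AAAAAAAAAAAA"; hapB <- "AAGAAAAACAAA"
  ct <- contig_of(hapA, hapA, hapA, hapB, hapB, hapB)
  calls <- call_snps(ct, "c1")
  expect_equal(nrow(calls), 2)
  sc <- coseg_scores(calls, ct)
  expect_equal(sc, c(1, 1))

  # a lone SNP has no siblings and scores 0
  lone <- call_snps(contig_of(hapA, hapA, "AAGAAAAAAAAA",
                              "AAGAAAAAAAAA"), "c2")
  expect_equal(coseg_scores(lone, contig_of(hapA, hapA, "AAGAAAAAAAAA",
                                            "AAGAAAAAAAAA")), 0)

  # k linked + 1 unlinked: linked score (k-1)/k, unlinked 0
  k <- 3
  hA <- "AAAAAAAAAAAAAAAA"; hB <- "AAGAAGAAGAAAAAAA"  # SNPs at 2,5,8
  # the unlinked variant (position 12) cuts across the haplotype split
  reads <- c(hA, hA, hB, hB,
             sub("^(.{12})A", "\\1T", hA), sub("^(.{12})A", "\\1T", hB))
  ct3 <- contig_of(reads[1], reads[2], reads[3], reads[4], reads[5],
                   reads[6])
  calls3 <- call_snps(ct3, "c3")
  expect_equal(nrow(calls3), k + 1)
  sc3 <- coseg_scores(calls3, ct3)
  linked <- calls3$pos %in% c(2, 5, 8)
  expect_equal(unname(sc3[linked]), rep((k - 1) / k, k))
  expect_equal(unname(sc3[!linked]), 0)
})

test_that("substitution summary reproduces ratio and frequency arithmetic", {
  s <- substitution_summary(27016, 38966, 4026, 334271)
  expect_equal(s$ts_tv_ratio, 27016 / 38966)
  expect_equal(s$ts_tv_ratio_2dp, 0.69)
  expect_equal(s$snp_freq_bp_int, 5)
  expect_equal(s$indel_freq_bp_int, 83)
  expect_equal(s$n_snp_total, 27016 + 38966 + 4026)

  eq <- substitution_summary(500, 500, 10, 10000)
  expect_equal(eq$ts_tv_ratio, 1)
  none <- substitution_summary(5, 0, 1, 1000)
  expect_true(is.na(none$ts_tv_ratio))
  expect_error(substitution_summary(1, 1, 1, 0), "positive")
})

test_that("every substitution call is exactly one of transition/transversion", {
  set.seed(71)
  lib <- make_est_library(n_transcripts = 60, read_lambda = 3,
                          transcript_len = c(300, 30),
                          read_len = c(240, 290),
                          ssr = ssr_spec(fraction = 0),
                          snp = snp_spec(p_snp = 0.02), seed = 71)
  calls <- call_snps_cluster_set(lib$clusters)
  subs <- calls[calls$kind == "substitution", ]
  expect_true(all(subs$subst_class %in% c("transition", "transversion")))
  expect_equal(sum(subs$subst_class == "transition") +
                 sum(subs$subst_class == "transversion"), nrow(subs))
  summ <- summarize_substitutions(calls, 1000)
  expect_equal(summ$n_ts + summ$n_tv, nrow(subs))
  # permutation invariance
  perm <- summarize_substitutions(calls[sample(nrow(calls)), ], 1000)
  expect_equal(summ$n_ts, perm$n_ts)
  expect_equal(summ$n_tv, perm$n_tv)
  expect_equal(summ$n_indel, perm$n_indel)
})

test_that("planted biallelic columns are fully recovered with no false calls", {
  lib <- make_est_library(n_transcripts = 80, read_lambda = 4,
                          transcript_len = c(400, 40),
                          read_len = c(320, 390),
                          ssr = ssr_spec(fraction = 0),
                          snp = snp_spec(p_snp = 0.015,
                                         indel_fraction = 0.08),
                          polya_fraction = 0, error_rate = 0, seed = 72)
  calls <- call_snps_cluster_set(lib$clusters)
  truth <- lib$truth$planted_snps
  key_call <- paste(calls$contig_id, calls$pos)
  key_truth <- paste(truth$contig, truth$pos)
  callable <- truth$callable
  expect_true(all(paste(truth$contig[callable],
                        truth$pos[callable]) %in% key_call))
  expect_equal(sum(!(key_call %in% key_truth)), 0)
  # planted class agrees with the called class
  m <- merge(calls, truth, by.x = c("contig_id", "pos"),
             by.y = c("contig", "pos"))
  expect_equal(m$kind == "indel", m$is_indel)
  subs <- m[!m$is_indel, ]
  expect_equal(subs$subst_class == "transition", subs$is_transition)
})

test_that("Ts/Tv estimate converges to the planted ratio at ~2000 SNPs", {
  lib <- make_est_library(n_transcripts = 350, read_lambda = 4,
                          transcript_len = c(450, 40),
                          read_len = c(380, 450),
                          ssr = ssr_spec(fraction = 0),
                          snp = snp_spec(p_snp = 0.025, p_transition = 0.5,
                                         indel_fraction = 0.05),
                          polya_fraction = 0, seed = 73)
  calls <- call_snps_cluster_set(lib$clusters)
  subs <- calls[calls$kind == "substitution", ]
  n <- nrow(subs)
  expect_gte(n, 2000)
  phat <- sum(subs$subst_class == "transition") / n
  se <- sqrt(0.5 * 0.5 / n)
  expect_lt(abs(phat - 0.5), 3 * se)
  # on the ratio scale the same bound maps through p/(1-p)
  expect_lt(abs(phat / (1 - phat) - 1),
            (0.5 + 3 * se) / (0.5 - 3 * se) - 1)
})

test_that("VCF output carries the calls with consensus as reference", {
  base <- "ACGTACGTACGT"; alt <- "ACGGACGTACGT"
  ct <- contig_of(base, base, base, alt, alt, alt)
  cs <- cluster_set(list(c1 = ct), est_set("s1", "GGCCGGCCGGCC"), "TST")
  calls <- call_snps_cluster_set(cs)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_snp_vcf(calls, cs, path)
  lines <- readLines(path)
  expect_equal(lines[1], "##fileformat=VCFv4.2")
  rec <- strsplit(lines[length(lines)], "\t")[[1]]
  expect_equal(rec[1], "c1")
  expect_equal(as.integer(rec[2]), calls$pos[1] + 1L)
  expect_match(rec[8], "CLASS=tv")
})
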