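#' Pipeline configuration
#'
#' A single declarative configuration object for [run_pipeline()]. Unknown
#' keys are rejected so that every behaviour-changing setting is visible in
#' the logged configuration echo.
#'
#' @param out_dir output directory for the report bundle.
#' @param library library label.
#' @param min_len,max_terminal_polyA EST cleanup settings (see
#'   [clean_est()]).
#' @param ssr_thresholds,min_mono_len SSR detection settings (see
#'   [find_perfect_ssrs()]).
#' @param max_gap compound-SSR chaining gap (nt).
#' @param min_depth,min_allele SNP calling settings (see [call_snps()]).
#' @param primer primer constraints from [primer_constraints()].
#' @param decile_fraction GC3 tail fraction.
#' @param precursor miRNA precursor thresholds from
#'   [precursor_thresholds()].
#' @param window_pad precursor folding context (nt).
#' @param precision "truncate" (table convention) or "round".
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, library = "NA",
                            min_len = 100, max_terminal_polyA = 12,
                            ssr_thresholds = c(`2` = 7, `3` = 5, `4` = 4,
                                               `5` = 4, `6` = 3),
                            min_mono_len = 14, max_gap = 100,
                            min_depth = 4, min_allele = 2,
                            primer = primer_constraints(),
                            decile_fraction = 0.10,
                            precursor = precursor_thresholds(),
                            window_pad = 40,
                            precision = c("truncate", "round")) {
  precision <- match.arg(precision)
  structure(as.list(environment()), class = "pipeline_config")
}

fmt_prec <- function(x, digits, precision) {
  if (precision == "truncate") trunc_dp(x, digits) else round(x, digits)
}

#' Run the full EST mining pipeline
#'
#' Orchestrates cleanup, assembly summary, SSR mining, ORF/primer design,
#' SNP calling, GC3 profiling (with GO enrichment when annotations are
#' supplied) and miRNA discovery (when a mature reference set is supplied),
#' writing one TSV per summary table plus GFF3/VCF artifacts into
#' `cfg$out_dir`. The bundle is a pure function of inputs and
#' configuration; no timestamps are embedded, so identical inputs produce
#' byte-identical output.
#'
#' @param ests EST set data.frame (the raw reads).
#' @param clusters a `cluster_set` for the library.
#' @param cfg a [pipeline_config()].
#' @param mirna_refs optional mature miRNA data.frame.
#' @param go_annotations optional data.frame (gene_id, go_id, ...).
#' @param domains optional named list mapping seq_id to a domain
#'   data.frame (domain_id, description, start, end in protein
#'   coordinates).
#' @return (invisibly) a list with every intermediate result.
#' @export
run_pipeline <- function(ests, clusters, cfg, mirna_refs = NULL,
                         go_annotations = NULL, domains = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  message("config: ", paste(sprintf("%s=%s", names(cfg),
                                    vapply(cfg, function(x)
                                      paste(format(unlist(x)), collapse = ","),
                                      character(1))), collapse = " "))

  message("stage clean")
  cleaned <- clean_est(ests, cfg$min_len, cfg$max_terminal_polyA)
  write_cleanup_report(cleaned$report, file.path(cfg$out_dir, "cleanup.tsv"))

  message("stage summarize")
  summ <- summarize_library(clusters)

  message("stage ssr")
  unigenes <- est_set(
    c(names(clusters$contigs), clusters$singletons$id),
    c(vapply(clusters$contigs, `[[`, character(1), "consensus"),
      clusters$singletons$seq),
    cfg$library)
  hits_raw <- find_perfect_ssrs(unigenes, cfg$ssr_thresholds,
                                cfg$min_mono_len)
  hits <- resolve_ssr_overlaps(exclude_polyAT(hits_raw))
  compounds <- merge_compound(hits, cfg$max_gap)
  freq <- repeat_frequency_table(hits)
  density <- ssr_density(sum(unigenes$length), nrow(hits))
  write_ssr_gff3(hits, file.path(cfg$out_dir, "ssr.gff3"))
  write_ssr_tsv(hits, file.path(cfg$out_dir, "ssr.tsv"))

  # before/after assembly SSR-EST rates
  pre_hits <- exclude_polyAT(find_perfect_ssrs(cleaned$kept,
                                               cfg$ssr_thresholds,
                                               cfg$min_mono_len))
  rate_before <- ssr_est_rate(nrow(cleaned$kept),
                              length(unique(pre_hits$seq_id)))
  rate_after <- ssr_est_rate(nrow(unigenes), length(unique(hits$seq_id)))
  table2 <- data.frame(
    stage = c("before_assembly", "after_assembly"),
    n_sequences = c(nrow(cleaned$kept), nrow(unigenes)),
    n_ssr_sequences = c(length(unique(pre_hits$seq_id)),
                        length(unique(hits$seq_id))),
    ssr_est_pct = fmt_prec(c(rate_before, rate_after), 2, cfg$precision))
  write_tsv(table2, file.path(cfg$out_dir, "table2_ssr_rates.tsv"))

  message("stage orf/primer")
  ssr_seq_ids <- unique(hits$seq_id)
  orfs <- list(); primer_rows <- list(); fdm_rows <- list()
  for (sid in ssr_seq_ids) {
    seq <- unigenes$seq[unigenes$id == sid]
    orf <- longest_orf_six_frames(seq, sid)
    orfs[[sid]] <- orf
    h <- hits[hits$seq_id == sid, , drop = FALSE]
    for (r in seq_len(nrow(h))) {
      loc <- classify_ssr_location(h$start[r], h$end[r], orf)
      pr <- design_primer_candidates(seq, h$start[r], h$end[r], cfg$primer)
      primer_rows[[length(primer_rows) + 1]] <- data.frame(
        seq_id = sid, unit = h$unit[r], ssr_start = h$start[r] + 1L,
        ssr_end = h$end[r], location = loc, status = pr$status,
        reason = if (pr$status == "fail") pr$reason else "",
        left_seq = if (pr$status == "ok") pr$left$seq else "",
        right_seq = if (pr$status == "ok") pr$right$seq else "",
        tm_l = if (pr$status == "ok") round(pr$left$tm, 2) else NA_real_,
        tm_r = if (pr$status == "ok") round(pr$right$tm, 2) else NA_real_,
        product_len = if (pr$status == "ok") pr$product_len else NA_integer_,
        stringsAsFactors = FALSE)
    }
    if (!is.null(domains) && sid %in% names(domains)) {
      fdm <- call_ssr_fdm(h, orf, domains[[sid]])
      if (nrow(fdm)) fdm_rows[[length(fdm_rows) + 1]] <- fdm
    }
  }
  primers <- if (length(primer_rows)) do.call(rbind, primer_rows) else NULL
  if (!is.null(primers))
    write_tsv(primers, file.path(cfg$out_dir, "primers.tsv"))
  fdms <- if (length(fdm_rows)) do.call(rbind, fdm_rows) else NULL
  if (!is.null(fdms)) write_tsv(fdms, file.path(cfg$out_dir, "ssr_fdm.tsv"))

  message("stage snp")
  calls <- call_snps_cluster_set(clusters, cfg$min_depth, cfg$min_allele)
  consensus_bp <- sum(vapply(clusters$contigs, function(ct)
    nchar(ct$consensus), integer(1)))
  snp_summary <- if (consensus_bp > 0) {
    summarize_substitutions(calls, consensus_bp)
  } else NULL
  if (nrow(calls)) {
    write_tsv(calls, file.path(cfg$out_dir, "snp.tsv"))
    write_snp_vcf(calls, clusters, file.path(cfg$out_dir, "snp.vcf"))
  }
  if (!is.null(snp_summary)) {
    table3 <- data.frame(
      parameter = c("total_snp_and_indels", "consensus_bp",
                    "transitions", "transversions", "indels",
                    "ts_tv_ratio", "snp_freq_bp", "indel_freq_bp"),
      value = c(snp_summary$n_snp_total, snp_summary$consensus_bp,
                snp_summary$n_ts, snp_summary$n_tv, snp_summary$n_indel,
                snp_summary$ts_tv_ratio_2dp, snp_summary$snp_freq_bp_int,
                snp_summary$indel_freq_bp_int))
    write_tsv(table3, file.path(cfg$out_dir, "table3_snp.tsv"))
  }

  message("stage gc3")
  orf_cds <- Filter(function(o) o$aa_len >= 30, orfs)
  gc_table <- NULL; comps <- NULL; enrich <- NULL
  if (length(orf_cds)) {
    cds <- data.frame(
      seq_id = vapply(orf_cds, `[[`, character(1), "seq_id"),
      seq = vapply(names(orf_cds), function(sid) {
        o <- orf_cds[[sid]]
        s <- substr(unigenes$seq[unigenes$id == sid], o$start + 1, o$end)
        if (o$frame < 0) revcomp(s) else s
      }, character(1)), stringsAsFactors = FALSE)
    comps <- codon_composition_set(cds)
    gc_table <- data.frame(
      library = cfg$library, n = nrow(comps),
      mean_len = round(mean(comps$length), 2),
      gc1 = round(mean(comps$gc1), 2), gc2 = round(mean(comps$gc2), 2),
      gc3 = round(mean(comps$gc3), 2), gc = round(mean(comps$gc), 2))
    write_tsv(gc_table, file.path(cfg$out_dir, "table6_gc.tsv"))
    if (!is.null(go_annotations) && nrow(comps) >= 10) {
      dec <- gc3_deciles(comps, cfg$decile_fraction)
      enrich <- tryCatch(
        go_enrichment(dec$high, dec$low, go_annotations),
        error = function(e) NULL)
      if (!is.null(enrich))
        write_tsv(enrich, file.path(cfg$out_dir, "table7_go.tsv"))
    }
  }

  mirna <- NULL
  if (!is.null(mirna_refs)) {
    message("stage mirna")
    screen <- homology_screen(unigenes, mirna_refs)
    cands <- lapply(seq_len(nrow(screen)), function(i) {
      sid <- screen$est_id[i]
      evaluate_precursor(unigenes$seq[unigenes$id == sid],
                         screen$start[i], screen$end[i],
                         est_id = sid, ref_id = screen$ref_id[i],
                         window_pad = cfg$window_pad,
                         thresholds = cfg$precursor)
    })
    write_candidate_tsv(cands, file.path(cfg$out_dir, "mirna_candidates.tsv"))
    mirna <- list(screen = screen, candidates = cands)
  } else {
    message("stage mirna skipped: no reference set")
  }

  freq_table1 <- render_table1(summ, freq, cfg$precision,
                               file.path(cfg$out_dir, "table1_summary.tsv"))

  invisible(list(cleaned = cleaned, summary = summ, unigenes = unigenes,
                 ssr_hits = hits, compounds = compounds, freq = freq,
                 density = density, rate_before = rate_before,
                 rate_after = rate_after, orfs = orfs, primers = primers,
                 fdms = fdms, snp_calls = calls, snp_summary = snp_summary,
                 gc = list(table = gc_table, comps = comps,
                           enrichment = enrich),
                 mirna = mirna, table1 = freq_table1))
}

#' Render the assembly/repeat summary table
#'
#' Emits the classic library summary rows (EST, contig, singleton and
#' unigene counts, redundancy and diversity indices, repeat-type counts
#' with percentages) as a two-column TSV, with values at reporting
#' precision alongside full precision.
#'
#' @param summ a `library_summary`.
#' @param freq a repeat frequency table from [repeat_frequency_table()].
#' @param precision "truncate" or "round".
#' @param path output TSV path (optional).
#' @return the table as a data.frame (invisibly written to `path`).
#' @export
render_table1 <- function(summ, freq, precision = "truncate", path = NULL) {
  cls <- freq$classes
  rows <- data.frame(
    parameter = c("Total number of EST", "Total number of contigs",
                  "Total number of ESTs left to assemble",
                  "Redundancy index (%)",
                  "Total number of unigenes sequences searched",
                  "Total number of SSRs",
                  "Diversity index (%)",
                  paste0(c("Mono", "Di", "Tri", "Tetra", "Penta", "Hexa"),
                         "-nucleotide")),
    value = c(summ$n_input, summ$n_contigs, summ$n_singletons,
              fmt_prec(summ$redundancy_index, 2, precision),
              summ$n_unigenes, freq$total,
              fmt_prec(summ$diversity_index, 1, precision),
              sprintf("%d (%s)", cls$n, fmt_prec(cls$pct, 2, precision))),
    full_precision = c(summ$n_input, summ$n_contigs, summ$n_singletons,
                       summ$redundancy_index, summ$n_unigenes, freq$total,
                       summ$diversity_index, cls$pct),
    stringsAsFactors = FALSE)
  if (!is.null(path)) write_tsv(rows, path)
  invisible(rows)
}

#' Simulate a preset synthetic library
#'
#' The `oyf-like` preset mirrors the shape of an ovary/young-fruit EST
#' library: ~3,800 transcripts of ~520 bp sampled to ~5,000 reads with a
#' large singleton fraction; `mf-like` mirrors a mature-fruit library with
#' higher redundancy and shorter unigenes. `scale` multiplies the
#' transcript count so that the same shape can be exercised at reduced
#' size.
#'
#' @param preset "oyf-like" or "mf-like".
#' @param seed RNG seed.
#' @param scale multiplier on the transcript count.
#' @return a synthetic library list (see [make_est_library()]).
#' @export
simulate_preset <- function(preset = c("oyf-like", "mf-like"), seed,
                            scale = 1) {
  preset <- match.arg(preset)
  if (preset == "oyf-like") {
    make_est_library(n_transcripts = max(20, round(3775 * scale)),
                     read_lambda = 0.34, transcript_len = c(520, 120),
                     library = "OYF", seed = seed)
  } else {
    make_est_library(n_transcripts = max(20, round(2529 * scale)),
                     read_lambda = 0.74, transcript_len = c(370, 90),
                     library = "MF", seed = seed)
  }
}
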