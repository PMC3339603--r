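# estminer

Marker mining and small-RNA discovery from EST libraries.

Expressed sequence tags — single-pass cDNA reads sampling a transcriptome —
remain the cheapest route to molecular markers for non-model crops. Given a
library of reads and an assembly (contigs + singletons), `estminer`
produces the classic survey outputs end to end:

- **SSRs**: maximal perfect microsatellites of 1–6 nt units at the standard
  thresholds (di ≥ 7, tri ≥ 5, tetra/penta ≥ 4, hexa ≥ 3 copies; mono
  ≥ 14 nt, poly-A/T excluded), compound-SSR chaining across ≤ 100 nt gaps,
  repeat-type frequency tables, and flanking primer candidates
  (18–27 nt, Tm 57–63 °C, GC 20–80%, penalty-minimal pairs).
- **Assembly indices**: redundancy index `100 (N − S)/N` and diversity
  index `100 (C + S)/N` for a library of `N` reads, `C` contigs, `S`
  singletons, with the truncation convention of the printed survey tables.
- **SNPs**: redundancy-based calling (≥ 2 reads per allele, depth ≥ 4) on
  contig alignment columns, a co-segregation (haplotype-consistency)
  score, transition/transversion ratios and SNP/indel frequencies
  (`Ts/Tv = n_ts/n_tv`, bp of consensus per event).
- **ORFs and SSR-FDMs**: longest stop-free stretch over six frames
  (standard code), ORF/non-ORF classification of SSRs, and SSR
  functional-domain markers from protein-domain annotations.
- **GC3 biology**: GC1/GC2/GC3 per coding sequence, top/bottom-decile
  selection by GC3, and 2×2 chi-square GO-term enrichment with high/low
  ratios.
- **miRNAs**: homology screen against a mature reference set (< 4
  mismatches, both strands), hairpin precursor validation under five
  criteria (arm location, MFE ≤ −25 and |MFEI| ≥ 0.85 with
  `MFEI = (MFE/len × 100)/GC%`, mature A+U in 30–70%, < 6 mature/star
  mismatches, duplex bulges ≤ 3 nt), and target prediction under the
  70%-of-perfect-MFE rule with ≤ 2 nt overhangs.
- **Synthetic libraries**: a seed-deterministic generator that plants
  SSRs, biallelic SNP columns with controllable Ts/Tv, GC3-controlled CDS
  sets and hairpin precursors, emitting full ground truth — every stage
  runs and is verified without downloads.

Folding/hybridisation energies come from a documented toy engine
(pair-count-maximising DP with stacking tie-breaks); structural criteria
are engine-agnostic and an external thermodynamic folder can be plugged
in. See the methods vignette (`vignettes/est-mining-methods.Rmd`) for the
model details and design choices.

## Worked example

```r
library(estminer)

# a dense synthetic library with planted ground truth
lib <- make_est_library(n_transcripts = 120, read_lambda = 4,
                        transcript_len = c(450, 40), read_len = c(380, 450),
                        ssr = ssr_spec(fraction = 0.3),
                        snp = snp_spec(p_snp = 0.01, p_transition = 0.5),
                        polya_fraction = 0.25, seed = 42)

summarize_library(lib$clusters)
#> library summary: 599 ESTs -> 119 contigs + 1 singletons (120 unigenes)
#>   redundancy index 99.83%  diversity index 20.0%

unigenes <- est_set(names(lib$clusters$contigs),
                    vapply(lib$clusters$contigs, `[[`, character(1),
                           "consensus"), "SYN")
hits <- resolve_ssr_overlaps(exclude_polyAT(find_perfect_ssrs(unigenes)))
head(hits, 3)
#>   seq_id  unit unit_len n_repeats start end canonical_unit
#> 1 T00001 ACGTG        5         6   254 284          ACGTG
#> 2 T00003   AAG        3         8    47  71            AAG
#> 3 T00004    AG        2         7   272 286             AG

calls <- call_snps_cluster_set(lib$clusters)
consensus_bp <- sum(vapply(lib$clusters$contigs,
                           function(ct) nchar(ct$consensus), integer(1)))
summarize_substitutions(calls, consensus_bp)
#> substitutions: 171 transitions, 177 transversions, 19 indels over 53636 bp
#>   Ts/Tv 0.96  1 SNP/154 bp  1 indel/2822 bp

design_primer_candidates(unigenes$seq[unigenes$id == hits$seq_id[1]],
                         hits$start[1], hits$end[1])$product_len
#> [1] 210
```

The indices read exactly as in a survey table: 599 reads collapsing to 120
unigenes give a redundancy index of `100 × (599 − 1)/599 = 99.83` (almost
every read was absorbed into a contig), and with planted transitions and
transversions equiprobable the estimated Ts/Tv of 0.96 sits near 1, one
substitution every 154 bp of consensus. The full orchestration —
cleanup → summary → SSR → ORF/primers → SNP → GC3/GO → miRNA, one TSV per
table plus GFF3/VCF — is `run_pipeline()`; a thin command-line wrapper
with `simulate`, `ssr`, `summarize`, `snp` and `run` verbs is installed at
`inst/cli/estminer`.

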