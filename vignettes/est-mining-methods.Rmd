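---
title: "Methods: mining EST libraries for markers and small RNAs"
author: "estminer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mining EST libraries for markers and small RNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(estminer)
```

## Scope and data model

estminer takes a set of single-pass cDNA reads (ESTs) per library,
optionally grouped into contigs by an external assembler, and derives the
classic transcriptome-survey products: microsatellite (SSR) markers with
flanking primers, redundancy-based SNP calls with substitution statistics,
codon-position GC profiles with GO enrichment, and homology-based miRNA
precursor and target candidates. Assembly itself is an input: a
`cluster_set` holds contig consensus sequences with gapped member-read
placements plus the unassembled singletons, and can be read from a plain
TSV. A naive greedy overlap clusterer exists only so that synthetic
libraries can exercise the full path without an assembler; it is quadratic
and not an assembler replacement.

Every coordinate is 0-based half-open internally; all written reports
(TSV, GFF3, VCF) are 1-based inclusive.

## Reporting convention

Derived percentages and ratios in the classic survey tables this package
mirrors are printed truncated toward zero rather than rounded (a
redundancy index of 56.289 prints as 56.28). `trunc_dp()` implements this,
summaries carry both the truncated and the full-precision value, and the
diversity index additionally exposes a rounded variant because published
tables have used either convention for that one quantity. Nothing
downstream consumes the truncated values; they exist for table fidelity.

## EST cleanup

Vector and quality trimming of dbEST records is upstream of this package
and undocumented in most survey reports. The cleanup stage therefore does
the minimal, explicit thing: a terminal 3' poly-A or 5' poly-T run is
clipped when it reaches `max_terminal_polyA` (default 12 nt, the point at
which a run is more plausibly a tail artifact than transcript sequence),
and records shorter than `min_len` (default 100 nt, a common dbEST
submission floor) are rejected with a reason code rather than an error.
Both knobs are configurable; nothing else is touched. IUPAC ambiguity
codes other than N are mapped to N on input so that downstream repeat and
translation logic sees a five-letter alphabet.

## SSR detection

The scanner reports every maximal run of a tandemly repeated primitive
unit of 1-6 nt meeting its class threshold: >= 7 copies for
dinucleotides, >= 5 for tri-, >= 4 for tetra- and penta-, >= 3 for
hexanucleotides, and >= 14 nt for mononucleotide runs. These are the
standard EST-SSR settings; note the penta threshold of four copies (20 nt)
is deliberately more permissive than the five many genome-scale tools use.
Intervals cover complete unit copies only and are left-aligned, so a run
like `(GAC)5` preceded by a `G` is reported from the `G` with unit `GAC`
rotated accordingly; motif identity is therefore compared through the
canonical (lexicographically minimal) rotation. Reverse complements are
*not* merged: `AG` and `CT` runs are distinct motif classes, as repeat-type
tables in the field tabulate them. Runs are broken at N, and a unit that is
itself a repetition of a shorter unit is suppressed in favour of the
primitive period.

Mononucleotide A and T runs are excluded from all tallies
(`exclude_polyAT()`): in cDNA data they are overwhelmingly residual mRNA
tails. The exclusion is deliberately narrow — AT dinucleotide repeats and
C/G homopolymers pass.

Compound microsatellites chain hits whose intervening non-repetitive
stretch is at most 100 nt (inclusive), transitively, with no restriction
on member unit lengths. Maximal runs of different periods can in rare
cases overlap by a shared edge base; since chaining requires disjoint
members, `resolve_ssr_overlaps()` keeps longer intervals first
(deterministic tie-breaks) and the pipeline applies it before merging.

SSR density is reported as kb of scanned sequence per SSR, computed from
the bases actually scanned — published totals for this quantity are not
generally recoverable from printed tables, so the package never
back-computes them.

## Assembly summary indices

For a library of $N$ input ESTs forming $C$ contigs and $S$ singletons:
redundancy index $= 100 (N - S) / N$ (percent of reads absorbed into
contigs), diversity index $= 100 (C + S) / N$ (percent represented by
unique unigenes). Contigs require at least two member reads; a one-read
"contig" is reclassified as a singleton so these identities stay exact.

## SNP calling

Calling is redundancy-based: an alignment column of a contig is a
candidate when its depth is at least `min_depth` (4) and at least two
distinct alleles each occur in at least `min_allele` (2) reads. A single
discordant read is treated as a sequencing error, never a variant. Columns
with more than two qualifying alleles keep the top two by count
(alphabetical tie-break, the gap symbol ordering first). A gap allele
makes the event an indel; runs of adjacent indel columns collapse to one
event, so a multi-residue deletion counts once. Substitutions are
transitions when the allele pair is within {A,G} or {C,T}, otherwise
transversions.

The co-segregation score asks whether a call helps define a haplotype: for
each sibling SNP column on the same contig whose bipartition keeps at
least two commonly covering reads on each side, the score counts the
fraction whose bipartition of those common reads equals this call's. A
contig's lone SNP scores 0. Perfectly linked planted SNPs score 1 by
construction, and with $k$ linked plus one recombinant column the linked
calls score exactly $(k-1)/k$ — the synthetic tests pin both.

Summary arithmetic: Ts/Tv $= n_{ts}/n_{tv}$; SNP frequency is consensus bp
per substitution; indel frequency is consensus bp per indel event.
Consensus size is the summed contig consensus length of the library.

The target organism of the motivating surveys is polyploid; ploidy-aware
genotyping, base qualities and genotype likelihoods are explicitly out of
scope — calls are descriptive column statistics.

## ORFs, primers, and domain markers

The putative coding segment of an EST is the longest stretch of codons
uninterrupted by a stop over all six frames of the standard genetic code,
with no ATG requirement (an ATG-anchored mode is behind a flag). Ties
break by frame order +1, +2, +3, -1, -2, -3, then leftmost forward-strand
start; only the stretch length is strand-symmetric, since equally long
stretches on either strand are resolved by that order. An SSR is
"in-ORF" when its interval overlaps the ORF's forward-strand projection by
at least one nucleotide (full containment is a flag — the choice is
genuinely open in the surveys this mirrors, and overlap is the more
inclusive default).

Primer candidates are an exhaustive scan of both flanks with windows of
18-27 nt: windows containing N, outside 20-80% GC, or outside 57-63 °C
melt are discarded, and the surviving pair minimising
$|len-20| + |T_m-60|$ (summed over both primers) within a 100-400 bp
product is returned, with deterministic tie-breaks. The melting
temperature is the Wallace rule below 14 nt and
$64.9 + 41(n_{GC} - 16.4)/len$ otherwise — a deliberate dependency-free
approximation; `tm_fun` accepts any replacement (e.g. a nearest-neighbour
adapter). Failures name the constraint that eliminated the most windows.
The product-size default reflects typical EST-SSR genotyping amplicons and
is configurable.

SSR functional-domain markers (SSR-FDMs) pair SSRs with protein-domain
annotations supplied as a table in protein coordinates. The default mode
is sequence-level (a sequence with at least one SSR and one domain yields
all pairs), matching how such markers are counted in surveys; a strict
mode projects the domain through the ORF frame to nucleotides
($p \mapsto [start + 3p, start + 3p + 3)$ forward, mirrored for reverse
frames) and requires overlap with the SSR.

## GC profiling and GO enrichment

GC1/GC2/GC3 are G+C fractions at each codon position over complete
codons, with N excluded position-wise from numerator and denominator.
For EST libraries the codons come from the predicted longest ORF. The
high/low sets are the top and bottom `ceiling(fraction * n)` genes by GC3
(default 10%), with seq_id tie-breaks for determinism and a guaranteed
disjointness check. Enrichment per GO term is a 2x2 chi-square (term
membership x high/low) with one degree of freedom and, by default, no
Yates correction — the published tables this mirrors include counts as
small as 2, which a continuity correction would smother; `correct = TRUE`
restores it. Per-term testing at alpha = 0.05 with no multiplicity
adjustment matches the survey convention; a Benjamini-Hochberg column is
available behind `fdr = TRUE`. GO graph propagation and annotation
transfer are out of scope: annotations are an input table. A
kernel-density mode profile of the GC3 distribution is exposed for
inspection but asserts nothing, since distribution shape claims in the
literature are qualitative.

## miRNA discovery

The homology screen slides each mature reference miRNA over both strands
of every EST and keeps, per (EST, reference) pair, the ungapped window
with the fewest Hamming mismatches (forward strand, then leftmost, on
ties) when that count is at most 3 — "fewer than four mismatches". T and
U are interchangeable. Local aligners used in the original surveys can
report slightly different match fractions at window edges; the Hamming
screen is exact for its own definition and that divergence is accepted.

### The toy energy engine

Folding and hybridisation use a deliberately simple engine: canonical
pairs score GC = -3, AU = -2, GU = -1 (wobble on by default), each
stacked pair adds -1, hairpin loops are at least 3 nt. Folding maximises
the number of pairs (Nussinov dynamic programming) and, among
equal-pair-count structures, minimises this energy — so contiguous
helices win ties. The reported "MFE" is the realised structure's energy.
These are toy thermodynamics: absolute kcal/mol from full
nearest-neighbour folders are *not* reproduced, and no published absolute
energy is claimed; the structural criteria layered on top are
engine-agnostic, and any object with the same fields can be swapped in as
an adapter to an external folder.

A consequence of pair-count maximisation is incidental pairing — isolated
pairs and tiny hairpins a thermodynamic model would reject. The precursor
diagnostics are therefore defined to be robust to it: the fold locates
the hairpin and its arms, but the mature/star mismatch count is the
minimum over ungapped registers of non-complementary positions against
the opposite arm (an antiparallel stem has constant position+partner sum,
so the register search is one-dimensional). This recovers planted
mismatch counts exactly through five mismatches; at six the register can
degrade, but the pass/fail boundary of the criterion below sits exactly
at six either way.

### Precursor criteria

A screened window, padded by `window_pad` (default 40 nt) of context, is
folded and must satisfy: (1) a hairpin with the mature sequence inside
one arm — external pairs agree on a side and at least half the mature
positions find registered counterparts in the opposing arm, which a
window spanning the terminal loop cannot do; (2) MFE at most -25 and
|MFEI| at least 0.85, where MFEI = (MFE/length x 100)/GC%; the survey
literature states only "lower than tRNA/rRNA", and these are the widely
used homology-screening defaults, configurable; (3) mature A+U content in
[0.30, 0.70] inclusive; (4) fewer than six mature/star mismatches; (5) no
bulge or loop over 3 nt inside the duplex.

### Targets

Target sites hybridise the mature sequence against every same-length EST
window, antiparallel and ungapped under the same pair/stack energies
(bulges are structurally zero; mismatch runs count as internal loops —
gapped duplexes belong to an external engine via the adapter). A site is
accepted when its energy reaches 70% of the perfect-complement energy
(the mature hybridised to its exact reverse complement), both end
overhangs are at most 2 nt, no internal loop exceeds 1 nt, and mature
positions 8-12 are fully paired. That last window is how this package
reads the classic helix constraint "-f 8 12": an interval in which
pairing is mandatory, not a bound on total helix length — a perfect
21-bp duplex must be acceptable, which a literal length bound of 8-12
would forbid.

## Synthetic libraries and what passing proves

`make_est_library()` generates transcripts (default 300 at ~520 +/- 120
bp, GC 0.45), plants one SSR in a configurable fraction in certified
repeat-free context (certification by an independent regex scan;
placements that scan as anything but exactly the planted run are
rejected and redrawn), assigns two haplotypes per transcript with
substitutions (transition probability `p_transition`) and 1-nt deletions
at non-adjacent positions, samples `1 + Poisson(lambda)` reads per
transcript with random offsets (the true cluster set falls out of the
offsets), applies optional per-base errors, and appends 3' poly-A tails
to a fraction of reads. Ground truth records every planted feature with
coordinates, plus per-variant coverage and a `callable` flag (>= 2 reads
per haplotype covering, depth >= 4). Everything is a pure function of
`seed`.

The `oyf-like` preset mirrors the shape of an ovary/young-fruit fruit EST
library — 3,775 transcripts at 521 +/- 120 bp under lambda = 0.34, i.e.
about 5,050 reads with a large singleton fraction; `mf-like` mirrors a
denser mature-fruit library (2,529 transcripts, 370 bp, lambda = 0.74).
Tests and the acceptance script run these presets at reduced `scale`
(0.01-0.05, a few hundred reads) and run dedicated generators sized to
their property — e.g. 350 transcripts at coverage ~8 for the
2,000-SNP transition-rate recovery, 200 genes x 300 codons for GC3
recovery — so the whole suite completes in minutes on one CPU.

What the generator does *not* emulate bounds what green tests mean:
reads have uniform error and no chromatogram-shaped quality decay, no
vector or adapter contamination, no chimeras; haplotypes are exactly two
per transcript (the motivating organism is polyploid); planted SNP
columns are never adjacent; hairpins are planted with spaced, homo-base
stem mismatches. Passing therefore demonstrates algorithmic correctness
against the stated definitions, not robustness to real trace data.

## Numerical and degenerate-input choices

Ratios with zero denominators (Ts/Tv with no transversions, density with
no SSRs, high/low ratio with an empty low cell) are reported absent (NA),
never infinite. Empty hit sets produce zero-count tables, not errors.
Tie-breaks are deterministic everywhere (documented per function), so
identical inputs give byte-identical report bundles; no timestamps are
written. The chi-square is undefined when a margin is empty and reported
NA. RNG use is confined to the synthetic module and every generator
requires an explicit seed.

## Known limitations

Assembly, BLAST annotation, InterProScan, Primer3 thermodynamics and
MFOLD/RNAhybrid energies are inputs or pluggable adapters, not
re-implementations. Absolute folding energies from the toy engine are not
comparable to published kcal/mol values. The greedy clusterer is for
synthetic tests only. Published headline counts from specific database
snapshots (total SSR/SNP yields of a given year's dbEST download) are
not reproducible from scratch and are not claimed; what the package
reproduces exactly is every derived statistic from printed table inputs,
and every detection property on data with known ground truth.
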