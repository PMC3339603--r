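Package: estminer
Title: Marker Mining and Small-RNA Discovery from EST Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Mines expressed sequence tag (EST) libraries for molecular
    markers and regulatory RNAs. Detects perfect and compound simple
    sequence repeats (SSRs) under configurable repeat-number thresholds,
    computes assembly redundancy and diversity indices, calls SNPs and
    indels from contig alignments by allele redundancy with a
    co-segregation (haplotype consistency) score and
    transition/transversion statistics, predicts six-frame open reading
    frames and designs SSR-flanking primer candidates, profiles codon
    position GC content (GC1/GC2/GC3) with chi-square GO-term enrichment
    of high- versus low-GC3 genes, and screens ESTs against mature miRNA
    reference sets with hairpin precursor validation (MFE, MFEI, A+U
    content, duplex mismatch limits) and target-site prediction. A
    seed-deterministic synthetic EST generator with planted ground truth
    lets every stage run and be verified without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
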