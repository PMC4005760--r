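Package: vdrmeta
Title: Consensus Summit Detection and DR3 Motif Screening for Multi-Sample
    VDR ChIP-seq Meta-Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for meta-analysis of vitamin D receptor (VDR) ChIP-seq
    peak sets across multiple cell types and stimulation states. Identifies
    consensus summit locations across samples by exact triangular-kernel
    summit density with span-based local-maximum selection, builds
    non-overlapping consensus peaks (<= 200 bp) by elongation and midpoint
    truncation, and assigns per-sample fold-enrichment and q-value metrics
    from original peaks or bedGraph score tracks. Implements pairwise
    peak-set overlap statistics with the more-than-50%-of-the-narrower-peak
    rule, stimulated/unstimulated partitioning and cell-type-specificity
    category counts, position-weight-matrix log-odds scanning for the
    classical DR3-type VDR-RXR response element (RGGTCANNGRGTTCA) around
    peak summits with threshold sweeps, summit-centred motif density
    profiles, fold-enrichment-ranked DR3 percentage curves and signed
    motif-to-SNP distances. Includes a seeded synthetic-data generator
    producing genome FASTA with planted motifs, per-sample narrowPeak files
    with jittered summits, and truth tables for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    GenomicRanges,
    jsonlite,
    yaml,
    knitr
Config/testthat/edition: 3
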