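Package: stromatac
Title: Chromatin Accessibility Dynamics and Alu Exaptation in Decidualizing Stromal Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end re-implementation of an ATAC-seq chromatin-accessibility
    analysis of decidualizing endometrial stromal cells: fragment counting in peaks,
    a negative-binomial differential-accessibility test with signed peak ranking,
    PWM scanning with exact score-distribution calibration, GC/CpG-matched background
    sampling and motif enrichment, strand-specific Tn5 cut-site footprint profiles,
    an ESR-bZIP-Pax triple-motif scanner, transposable-element overlap statistics in
    consensus coordinates, flank-based Alu presence/absence calling across primate
    genomes, and peak-to-gene expression association. A synthetic-data module
    generates every input with planted ground truth so the whole pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    data.table,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    jsonlite,
    yaml
Config/testthat/edition: 3
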