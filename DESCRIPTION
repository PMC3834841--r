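Package: wellington
Title: Strand-Aware Digital Genomic Footprinting for DNase-Seq Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects transcription-factor footprints in DNase-seq data by
    testing for strand-imbalanced depletion of 5' cut counts inside candidate
    footprints relative to flanking shoulder regions (the Wellington
    statistic), in forward, reverse-control and strand-agnostic (1D) modes.
    Provides per-base scoring of DNase I hypersensitive sites, greedy
    non-overlapping footprint calling with WIG and BED output, validation
    metrics (reciprocal-containment recapitulation, ROC/AUC, positive
    predictive value, nucleotide performance coefficients, signal and motif
    aggregation over footprints), strand-resolved average cut profiles and
    imbalance heat-map matrices, and a seeded simulator of hypersensitive
    sites with planted, strand-imbalanced footprints for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicAlignments,
    GenomicRanges,
    ggplot2,
    IRanges,
    purrr,
    rlang,
    Rsamtools,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
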