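Package: hushmap
Title: Classification and Signal Profiling of HUSH Chromatin Targets
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for multi-omic classification and profiling of chromatin
    targets of the human silencing hub (HUSH) complex. Consolidates ChIP-seq
    peak sets across factors with a one-dimensional mean-shift procedure,
    tests regions for H3K9me3 enrichment with a negative-binomial Wald test
    using median-of-ratios size factors, classifies regions into
    H3K9me3-positive HUSH, H3K9me3-negative HUSH, and MPP8-only classes, and
    orients them by nascent-transcription strand ratio. Provides
    coverage-heatmap matrices with depth scaling, bootstrap aggregate
    profiles, differential and unit-scaled maps, peak centroid-shift and
    transcriptional readthrough statistics, repeat/trinucleotide/TSS/TTS
    annotation enrichment, CLIP RT-stop enrichment normalized for feature
    length and transcription, and a synthetic multi-assay data generator
    with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
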