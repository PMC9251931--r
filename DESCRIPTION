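Package: depthsat
Title: Sequencing-Depth Saturation Analysis of Coding and Noncoding Transcript Assembly
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluation framework for studying how sequencing depth affects the
    recovery of coding versus noncoding transcripts from reference-based
    transcript assembly. Provides GTF/BED/count-matrix readers with fixed
    coordinate conventions, a synthetic transcriptome and depth-dependent
    assembly-detection simulator, intron-chain matching with exon and splice
    completeness scoring, class-stratified sensitivity and precision,
    transposable-element overlap annotation, recurrence filtering across
    samples, loess-based saturation and per-increment statistics,
    expression-ranked cumulative curves, and single-cell detection statistics
    with median-of-ratios normalization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    Matrix,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    DESeq2,
    rtracklayer,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
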