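Package: scwgaeval
Title: Evaluation of Single-Cell Whole-Genome Amplification Performance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Benchmarks single-cell whole-genome-amplification (WGA) methods
    (MDA, MALBAC, DOP-PCR) from their downstream sequencing summaries.
    Implements golden-control genotype concordance (consensus genotype
    detection efficiency, concordant ratio, allele drop-out and
    false-positive ratios, SNV detection efficiency), read-depth
    uniformity diagnostics (normalized window depth, Poisson reference,
    cumulative depth, GC strata, repeat-region depth, reproducibility
    correlations), a binned copy-number pipeline (mappability bins, GC
    correction, circular binary segmentation, mode anchoring to diploid,
    CNV calls, in-silico CNV spike-in and overlap-length
    sensitivity/specificity), chimeric-breakpoint classification against
    a bulk control, and a synthetic-data generator that emulates
    WGA-method-specific biases so every analysis runs without external
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    yaml,
    jsonlite,
    withr,
    stats,
    utils,
    Rcpp,
    GenomicRanges,
    IRanges,
    S4Vectors
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
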