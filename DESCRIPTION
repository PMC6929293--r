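Package: mosaicnv
Title: Somatic Copy-Number Mosaicism from FISH Counts and Single-Cell
    Whole-Genome Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies somatic copy-number mosaicism in brain tissue from
    two complementary assays. For fluorescence in-situ hybridisation (FISH)
    count tables it computes per-group mosaicism fractions with exact
    binomial confidence intervals and the full set of 2x2 association
    statistics (Fisher's exact test, Yates-corrected chi-square, relative
    risk with Katz intervals, odds ratio with Woolf intervals). For
    single-cell whole-genome bin counts it provides a transparent
    copy-number caller: normalisation, recursive binary segmentation with
    permutation tests, integer-ploidy fitting, MAPD/confidence quality
    gates, a three-component Gaussian-mixture copy-number filter, and
    rule-based call filtering. Downstream analytics cover clonality
    detection, gain/loss composition, inclusion association, gene overlap
    annotation, and boundary-feature enrichment against random genomic
    regions. A seeded synthetic-data generator emulates amplified
    single-cell read-count profiles and FISH counts with known ground
    truth, so the whole pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
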