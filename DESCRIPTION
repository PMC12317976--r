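Package: phosphoflow
Title: Differential Analysis of TMT Phosphoproteomics Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for quantitative analysis of
    TMT-multiplexed phosphoproteomics and cell-type proteomics data.
    Aggregates peptide spectral matches into phosphopeptide intensity
    profiles, normalises phospho signal by input-proteome abundance,
    applies a calibrated generalized-log variance-stabilizing transform,
    removes batch effects, imputes missing values by k-nearest neighbours
    with provenance tracking, and tests for differential abundance with
    imputation-weighted linear models and empirical-Bayes variance
    moderation. Includes two-tier hit/candidate classification, k-means
    clustering with elbow-based model selection, term-enrichment odds
    ratios, Spearman sample clustering, cell-type specificity calls, and
    a synthetic-data generator with ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    limma,
    withr,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
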