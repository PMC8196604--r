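Package: varstab
Title: Benchmarking Stability and Pathogenicity Predictors for Cancer Missense Variants
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to evaluate computational predictors of protein stability
    change (folding free energy difference, ddG) and variant pathogenicity on
    curated sets of missense variants in cancer-related genes. Provides a
    tabular data model for single amino acid variants with experimental ddG,
    melting-temperature shifts, predicted ddG, pathogenicity scores, relative
    solvent accessibility, residue conservation and Cancer Mutation Census
    tier annotations; regression and binary-classification metrics with
    balanced-rate threshold optimization and stratified cross-validation;
    enrichment statistics (Fisher exact, two-sample Kolmogorov-Smirnov,
    exact binomial quadrant tests); structural feature helpers (relative
    solvent accessibility normalization, alignment-column conservation); a
    calibrated synthetic-dataset generator for end-to-end testing; and a
    pipeline that runs the full evaluation and writes tidy reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    readr,
    rlang,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    Biostrings,
    optparse
Config/testthat/edition: 3
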