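Package: targetmr
Title: Drug-Target Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for two-sample drug-target Mendelian
    randomization from GWAS summary statistics. Builds cis genetic instruments
    around a drug-target gene (significance, LD clumping, minor-allele
    frequency, instrument-strength and outcome-overlap filters, with per-SNP
    variance explained and F statistics), harmonizes exposure and outcome
    effects onto a shared effect allele, and estimates causal effects with
    inverse-variance weighted, MR-Egger and weighted-median methods together
    with Cochran's Q heterogeneity, the Egger intercept pleiotropy test,
    MR-PRESSO outlier detection with post-removal re-estimation, and
    leave-one-out sensitivity analysis. Ships a seeded synthetic two-sample
    GWAS generator with known causal effects, pleiotropy regimes, planted
    outliers and block LD, so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
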