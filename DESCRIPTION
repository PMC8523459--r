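Package: epiage
Title: Epigenetic Age Prediction and Age Acceleration from Targeted
    Bisulfite Amplicon Methylation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Methylation calling and quality control from targeted bisulfite
    amplicon read counts over an eight-marker, 44-CpG age panel; linear
    CpG-based age predictors (a six-CpG blood model and a single-CpG
    MIR29B2CHG model); group comparisons of prediction accuracy from raw
    values or printed summary statistics using the pooled two-sample t
    machinery; epigenetic age acceleration as residuals of predicted age on
    chronological age with covariate-adjusted group association; and a
    matched case-control cohort simulator with age-dependent methylation,
    group-specific shifts and binomial read-count noise, so the full
    analysis is testable end to end without access to the original samples.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
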