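Package: paneldx
Title: Diagnostic Biomarker Panel Selection with Genetic Algorithms and
    IDI-Gated Stepwise Search
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds compact logistic-regression diagnostic panels from wide
    multimodal biomarker tables (imaging, fluid assays, clinical flags) with
    missing data. Implements z-standardization and per-contrast missingness
    filtering, a genetic-algorithm wrapper search scored by cross-validated
    classification accuracy, correlation-merged feature-frequency ranking,
    forward selection and backward elimination gated by the integrated
    discrimination improvement (IDI) statistic, a-posteriori validation-set
    construction with calibration/test splitting, bootstrap performance
    intervals, and a random-model null experiment. Includes a synthetic
    cohort generator with planted effect sizes, correlated duplicate
    features, and missing-completely-at-random masks so the whole pipeline
    can be exercised with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
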