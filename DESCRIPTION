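Package: elevox
Title: County-Level Ecological Regression of Cancer Incidence on
    Population-Weighted Elevation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for county-level ecological analysis
    of cancer incidence against elevation used as an ambient-oxygen proxy.
    Provides population-weighted zonal exposure computation over raster grids,
    county quality-control filters with a divergence diagnostic,
    square-root-population weighted least squares with one-tailed inference,
    exhaustive best-subset selection under BIC with a forced exposure
    covariate, weighted lasso with 10-fold cross-validation and the
    one-standard-error rule, smoking-tercile and state stratification with
    fixed-effects meta-analysis and I-squared, environmental-substitution
    Bayes factors from BIC differences, and a calibrated synthetic county
    generator so every stage is testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
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
    glmnet,
    metafor,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
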