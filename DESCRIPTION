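Package: dfclink
Title: Linking Dynamic Functional Connectivity Variability to Behavioral
    and Cognitive Dimensions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to relate the temporal variability of resting-state
    functional connectivity to behavioral and cognitive dimensions in a
    multivariate framework. Implements sliding-window and flexible
    least squares (FLS) dynamic connectivity variability estimates from
    parcellated time series, confound residualization, Relief-based and
    PCA feature reduction, sparse canonical correlation analysis via
    penalized matrix decomposition with permutation significance,
    FDR control and bootstrap stability selection, network-level loading
    aggregation, and mediation analysis of connectivity effects on
    behavior through cognition with percentile bootstrap confidence
    intervals. Ships a synthetic-cohort generator with planted ground
    truth for end-to-end validation and parameter-recovery testing.
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
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
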