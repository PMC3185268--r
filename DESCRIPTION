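Package: ivtriage
Title: Instrumental-Variable and Propensity-Score Analysis of ICU Triage Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for estimating the causal effect of intensive-care
    admission on in-hospital mortality from observational triage cohorts.
    Provides crude and covariate-adjusted regression, propensity-score caliper
    matching without replacement, candidate-instrument diagnostics (partial
    F-statistic, partial r-squared, instrument-stratified covariate balance),
    and five instrumental-variable estimators for a binary outcome (Wald,
    two-stage least squares, two-stage logistic, two-stage probit with the 1.6
    rescaling, and three-stage least squares) with percentile-bootstrap
    inference and optional cluster resampling. A built-in synthetic cohort
    generator with known causal structure (true treatment effect, latent
    confounder, valid binary instrument) makes every stage testable without
    access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    MASS,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
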