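Package: burstvar
Title: Bayesian Bivariate Vector Autoregression for Measurement-Burst Daily Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation, preprocessing and Bayesian estimation for bivariate
    daily time series collected in measurement-burst designs, motivated by
    studies pairing evening life-satisfaction ratings with wearable-derived
    physical activity. Includes a synthetic-data generator (minute-level step
    streams, evening surveys, burst calendars), wear-time preprocessing
    (steps per valid wear-hour), response transforms and covariate encoding
    with weekly and annual periodicity, a hierarchical vector-autoregressive
    model of order one with person random intercepts and a contemporaneous
    disturbance correlation moderated through a Fisher-z link, a blocked
    Gibbs sampler with full-information handling of missing responses,
    convergence diagnostics, effect tables, prior-sensitivity and
    parameter-recovery harnesses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    coda,
    ggplot2
Config/testthat/edition: 3
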