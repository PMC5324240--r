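Package: qhspm
Title: Quadratic-Hazard Stochastic Process Models for Longitudinal and
    Time-to-Event Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint modelling of repeatedly measured biomarkers and
    time-to-event outcomes with stochastic process models (SPM) in which a
    mean-reverting process drives a quadratic (U-shaped) hazard. Provides
    maximum-likelihood estimation for discrete-time, continuous-time and
    one-dimensional time-dependent-coefficient model variants, exact
    coefficient conversion between the discrete and continuous
    parameterizations, a moment-ODE likelihood evaluated with a compiled
    Runge-Kutta core, cohort microsimulation under both observational
    plans, Kaplan-Meier projection summaries, and data-preparation
    utilities for long-format follow-up tables.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    survival,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
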