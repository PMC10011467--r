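Package: windkessel
Title: Three-Element Windkessel Parameter Identification and Non-Invasive
    Estimation for Aortic Arch Branch Arteries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying three-element Windkessel (RCR) outflow
    boundary-condition parameters of aortic-arch branch arteries from paired
    single-period flow and pressure waveforms, normalizing them into
    dimensionless transferable form, and estimating patient-specific
    parameters non-invasively from brachial cuff pressure, heart rate, and
    mean flow or vessel diameter using cohort-derived normalized parameter
    tables. Includes a fixed-step Runge-Kutta forward model (flow to
    pressure) and its inverse direction (pressure to flow), constrained
    nonlinear least-squares fitting with the total resistance held at mean
    pressure over mean flow, Monte Carlo sensitivity mapping of the
    pressure-match cost over the normalized parameter plane, and an
    artery-specific synthetic cohort generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
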