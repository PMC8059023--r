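Package: hrdyn
Title: Identification and Comparison of Heart-Rate Dynamics Models for
    Treadmill Exercise
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying linear time-invariant models of the
    heart-rate response to treadmill speed and for comparing first-order
    (single mean-response-time) against second-order (separate Phase I and
    Phase II) model structures. Provides pseudo-random binary sequence
    (PRBS) excitation design with balanced evaluation-window selection,
    simulation of virtual participants with physiological heart-rate
    variability and slow drift, preprocessing (downsampling, windowing,
    detrending), continuous-time transfer-function estimation by
    simulation-error least squares with exact zero-order-hold
    discretisation, counterbalanced cross-validation with NRMSE fit and
    RMSE outcomes, and the paired one-sided statistical comparison of the
    two model classes.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    nortest,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
LinkingTo: Rcpp
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
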