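Package: boundshift
Title: Confidence-Dependent Adjustment of Decision Bounds in Diffusion Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for studying how decision confidence on one trial shapes the
    speed-accuracy tradeoff on the next within the drift-diffusion model (DDM).
    Provides an analytic Wiener first-passage-time kernel with a seeded
    Euler-Maruyama simulator, a synthetic multi-participant cohort generator with
    post-decisional confidence, slow 1/f performance drift and EEG-like (Pe/ERN)
    amplitudes, model-free response-caution statistics, a hierarchical Bayesian
    regression DDM with confidence- or EEG-coded bound and drift, drift-corrected
    sequential-effect summaries with posterior-overlap p-values, matched-trial
    controls, and single-trial EEG covariate preparation (windowed amplitudes,
    rank transforms, residualization and quantile binning).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    generics,
    ggplot2,
    readr,
    jsonlite,
    signal,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
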