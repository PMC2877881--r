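Package: scrlti
Title: Linear Time-Invariant Modelling of Skin Conductance Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for model-based analysis of event-related skin conductance
    responses (SCRs) under the assumption that electrodermal activity is the
    output of a linear time-invariant system. Provides zero-phase Butterworth
    band-pass preprocessing, an exponentially modified Gaussian canonical
    response function with time and dispersion derivative basis functions,
    convolution (stick-function) design matrices with least-squares amplitude
    estimation, principal-component estimation of empirical response functions
    with within/between-subject variance partitioning, time-lagged cross-site
    correlation, a repetition-by-ISI linearity analysis, and a synthetic
    skin-conductance simulator with known ground truth for validating every
    analysis stage. A command-line interface exposes the full pipeline.
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
    pracma,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
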