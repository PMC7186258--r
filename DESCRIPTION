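Package: lvgvar
Title: Latent-Variable Graphical Vector-Autoregression Models for
    Time-Series and Panel Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimation of graphical vector-autoregression models between
    latent variables from single-subject time-series data (ts-lvgvar) and
    multi-wave panel data (panel-lvgvar). Temporal effects are modeled with a
    lag-1 coefficient matrix and contemporaneous and between-subject structures
    as Gaussian graphical models (partial-correlation networks). Models are fit
    by maximum likelihood or full-information maximum likelihood on
    (block-)Toeplitz moment structures, with chi-square fit assessment, RMSEA
    and incremental fit indices, significance pruning with multiplicity
    adjustments, modification-index-guided step-up search, BIC-optimizing
    stepwise model search, case-drop bootstrap stability analysis, and
    generative simulators for both settings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
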