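Package: sctperm
Title: Score-Based Structural Change Tests with Permutation Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Score-based structural change tests (SCTs) of parameter
    invariance across subgroups of an auxiliary ordering variable, for
    linear regression models and saturated Gaussian graphical models.
    Provides per-observation maximum-likelihood scores, decorrelated
    empirical fluctuation processes, the double-maximum (DM),
    Cramer-von Mises (CvM) and maximum-Lagrange-Multiplier (maxLM)
    statistics with tail trimming, p values from a simulated
    Brownian-bridge null as well as from a Monte Carlo permutation
    null, and a simulation engine for type-I-error calibration and
    power studies of both approaches.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    MASS,
    Rcpp,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
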