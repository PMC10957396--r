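Package: glampi
Title: Generative Linear-Angular Modelling of Path Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing immersive-VR triangle-completion experiments
    with a generative linear-angular model of path integration (GLAMPI). The
    package covers the full pipeline: simulation of synthetic cohorts with
    realistic trial geometry, standardisation of raw head-tracking trials,
    proportional linear and angular error metrics, maximum-likelihood fitting
    of a seven-parameter leaky-integrator model of encoding, calculation and
    production errors, AIC/BIC model selection over a candidate lattice,
    group-level inference, and linear-SVM classification of clinical groups
    with cross-validated ROC curves and DeLong tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    jsonlite,
    lhs,
    e1071,
    car,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    deSolve,
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
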