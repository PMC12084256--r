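Package: qssa
Title: Accuracy and Predominance Diagnostics for Quasi-Steady-State
    Approximations of Michaelis-Menten Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for assessing the validity of quasi-steady-state
    approximations (QSSAs) of the irreversible Michaelis-Menten reaction
    mechanism. Implements the planar mass-action model, five reduced
    models (standard QSSA, slow-product QSSA, Kumar-Josic, Calder-Siegel,
    and the piecewise reverse QSSA), phase-plane nullclines and fence
    curves with anti-funnel (trapping region) construction, dimensionless
    timescale-separation indicators, rigorous substrate-depletion rate
    bounds, and an empirical predominance ranking that compares reduced
    models against stiff numerical solutions of the full system.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
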