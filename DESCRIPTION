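Package: dlmra
Title: Dynamic Least-Squares Modular Response Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers signed, directed, weighted network edges -- including
    self-regulation, basal production and external-stimulus terms -- from
    perturbation time-course data by fitting a dynamic network model with
    bounded multistart least squares (DL-MRA).  Ships the experimental-design
    simulators used to validate the method (stable random linear networks,
    Hill-kinetics feedforward-loop gene circuits, Markov cell-state transition
    models, proportional Gaussian noise), a direct per-time-point analytic
    solver, constrained estimator variants, and a bootstrap percentile-window
    classifier with ROC-based window selection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    minpack.lm,
    pracma,
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
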