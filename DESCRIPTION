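Package: bifdesign
Title: Automated Design of Gene Circuits with Prescribed Saddle-Node
    Bifurcation Diagrams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Optimization-based design of synthetic gene regulatory circuits
    whose bifurcation diagrams contain saddle-node points at prescribed
    locations, including mushroom-shaped diagrams (four folds, two bistable
    signal ranges) and isolas (closed equilibrium branches). Encodes a
    mixed-integer circuit superstructure as a thermodynamic ODE model with
    Hill-type signal inputs, detects folds through the null vector of the
    extended Jacobian, traces and classifies bifurcation diagrams by
    dense-seeded root sweeps, searches circuit topologies and kinetic
    parameters by seeded multistart constrained least squares, scores
    topology robustness by covariance log-determinant and interquartile-range
    spread with bootstrap uncertainty, computes Pareto fronts of robustness
    versus wiring complexity, and simulates biosensor, timer and
    irreversible-memory behaviors under time-varying signals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
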