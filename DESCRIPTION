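Package: dmmsort
Title: Stochastic Lattice Simulation of Multi-Type Cell Sorting and the
    Effective Adhesion Parameter
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Event-driven simulation of the Differential Migration Model, a
    probabilistic cellular automaton in which adjacent cells of unlike type
    exchange positions at rates suppressed or enhanced by type-specific bond
    strengths. Provides the order indicator that quantifies segregation of a
    lattice configuration, the derived system parameters of a bond-strength
    vector (scaling parameter, effective adhesion parameter and convergence
    speed parameter for any number of cell types), exact jump-chain analysis
    on small lattices, seeded parameter sweeps, and symmetry-reduced linear
    classification (support vector machine and logistic regression) that
    recovers the effective adhesion parameter from simulated time series.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    e1071
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
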