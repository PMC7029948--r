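Package: StabilityBasin
Title: Stability Basins for Sit-to-Stand via Zonotope Backward Reachability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Individualised stability analysis of the Sit-to-Stand motion.
    Fits data-driven controller models (finite-horizon LQR, feed-forward plus
    feedback, and a set-valued input-bounds model) for a telescoping inverted
    pendulum model of the body centre of mass, computes the time-varying set
    of states that can still reach standing (the Stability Basin) by zonotope
    backward reachability, and predicts per-trial success or failure with a
    leave-one-out protocol. Includes a synthetic Sit-to-Stand experiment
    generator with known ground-truth controllers and outcome labels.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    expm,
    signal,
    quadprog,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    MASS,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'StabilityBasin-package.R'
    'core-model.R'
    'controllers.R'
    'zonotope.R'
    'reachability.R'
    'evaluation.R'
    'io.R'
    'synthetic.R'
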