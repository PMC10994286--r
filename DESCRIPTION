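Package: sorsvf
Title: Sequentially Optimized Reconstruction Strategies for Visual Field Testing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for simulating and optimizing perimetric (visual field)
    testing on the 24-2 grid. Implements the sequentially optimized
    reconstruction strategy (SORS) meta-strategy with ordinary linear
    regression, transformed-target principal component regression (TTPCR),
    partial least squares and hill-of-vision baselines; Bayesian (ZEST) and
    4-2 staircase threshold estimation with simulated responders of
    configurable reliability; quadrant-seeding growth baselines; a synthetic
    glaucomatous visual field generator; and a cross-validated Monte Carlo
    evaluation harness with severity stratification and embedding-dimension
    sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
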