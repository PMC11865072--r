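Package: gblupdesign
Title: Optimal Training-Set Design for Genomic Prediction Under the gBLUP Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for choosing the training population in genomic best linear
    unbiased prediction (gBLUP). Implements the mixed-model-equation covariance
    machinery for a given design (prediction error variances, the fixed-effect
    annihilating projection, and generalized coefficients of determination),
    scalar design criteria on the random-effect block (D-criterion, CDMin,
    CDMean), and exact-design search by classical and modified Fedorov exchange
    with configurable support-set orderings, a random-swap hill-climbing
    baseline, a multi-restart driver and an exhaustive enumeration oracle.
    Includes a synthetic marker and genomic-relationship-matrix generator so
    all benchmarks run without external data, plus a command-line interface
    for simulation, optimization and reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
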