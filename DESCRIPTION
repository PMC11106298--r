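Package: gnna
Title: Grey Wolf Optimizer Trained Neural Networks for Species
    Distribution Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits species distribution models with a three-layer
    feedforward neural network whose weights and biases are found by the
    Grey Wolf Optimizer metaheuristic (the GNNA hybrid), alongside a
    plain backpropagation baseline.  Includes the full presence /
    pseudo-absence preparation and evaluation protocol (spatial thinning
    of occurrence records, 3x pseudo-absence sampling, Pearson
    correlation variable screening, repeated stratified 80/20 splits,
    AUC, Cohen's kappa and the true skill statistic with the
    TSS-maximizing threshold), a virtual-species simulator with known
    ground truth for validation, ESRI ASCII grid raster input/output,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    geosphere,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
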