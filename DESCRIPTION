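Package: orthodesign
Title: Insulated Promoter Design with Host-Effect Purification and
    Convolutional Activity Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for designing insulated (host-independent) phage-polymerase
    promoters from paired induced/uninduced expression measurements. Implements
    the three-step purification that removes host RNA-polymerase activity from
    a promoter library (computational host filter, responsiveness filter,
    subtraction of uninduced from induced activity), a convolutional
    sequence-to-activity predictor trained by stochastic gradient descent
    (with CNN-LSTM, attention and linear baselines), semi-rational design of
    defined-strength promoter sets from bounded-mutation pools, de novo design
    by gradient ascent on a relaxed one-hot encoding, activity-landscape and
    optimization-route visualization, and convolutional-kernel motif
    extraction with clustering. A built-in synthetic cis-trans simulator (a
    smooth orthogonal activity landscape plus a rugged host landscape with
    replicate measurement noise) provides ground truth so the full pipeline
    runs without wet-lab data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    Biostrings,
    cluster,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp, RcppArmadillo
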