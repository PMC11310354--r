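Package: strainkit
Title: Two-Stage Deep-Learning Strain Estimation for Ultrasound Image
    Sequences of Tendon
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates full-field two-dimensional strain maps (longitudinal,
    transverse, and shear) from pairs of ultrasound-like grayscale images of
    soft tissue under load.  A two-stage pipeline first classifies each image
    pair as tension, compression, or rigid-body motion with a convolutional
    classifier, then routes the pair to a class-specific encoder-decoder
    regression network that outputs the per-pixel strain tensor.  The package
    also provides a synthetic speckle-image data engine with exact ground-truth
    deformation fields for training and benchmarking, classical subset-based
    digital image correlation (DIC) and direct deformation estimation (DDE)
    baselines, strain-error metrics with permutation tests, and downstream
    tendon mechanics (bulk strain, stress, and apparent modulus).  All neural
    network primitives are implemented natively with 'RcppArmadillo'.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    tiff,
    png,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
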