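Package: ihcprior
Title: Stain-Deconvolution Prior-Guided Classification of Immunohistochemistry Patches
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for semi-quantitative analysis of DAB immunohistochemistry
    (IHC) patch images. Implements Ruifrok-style colour deconvolution in
    optical-density space (Lambert-Beer law) to produce single-channel DAB
    "colour anomaly maps"; a Lambert-Beer forward simulator of
    hematoxylin-counterstained patches with controlled DAB intensity and area
    fraction, scored on the standard intensity (0-3) plus proportion (0-4)
    scale; a feature-importance attention module over a convolutional
    backbone; and a two-branch classifier that fuses attention-weighted image
    features with features extracted from the anomaly map. A compact neural
    network engine (convolution, pooling, batch/layer normalisation, SGD with
    momentum and backpropagation) is included so the full pipeline trains and
    evaluates on synthetic data with no external dependencies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    png,
    yaml,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    tiff,
    EBImage,
    optparse
Config/testthat/edition: 3
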