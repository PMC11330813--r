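Package: maresnet
Title: Multi-Scale Attention Residual Networks for Lesion Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds, trains and evaluates multi-scale attention residual
    encoder-decoder networks (MARes-Net) for binary lesion segmentation of
    grayscale radiograph-like images. Provides the residual U-Net backbone and
    its attention components (squeeze-and-excitation, channel/spatial/CBAM
    attention, attention gates), a scale-aware feature extraction module built
    from dilated convolution branches, and a multi-scale compression-excitation
    module with top-down context fusion. Includes a reverse-mode automatic
    differentiation engine with C++ convolution kernels, Dice-loss training
    with Adam, segmentation metrics (precision, recall, IoU, F1), paired
    image/mask input-output with geometric augmentation, and a synthetic
    generator of radiograph-like lesion images with exact ground-truth masks
    for testing and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    yaml,
    optparse,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
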