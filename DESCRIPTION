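Package: upaint
Title: Accelerated DNA-PAINT Super-Resolution Reconstruction with a U-Net
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for accelerating DNA-PAINT single-molecule localization
    microscopy by reconstructing dense super-resolution images from sparse
    localization renders, optionally paired with widefield images. Includes a
    random-walk microtubule simulator for generating training data, readers
    and quality filters for Picasso-style localization tables with
    oversampled histogram rendering, tiling/filtering/normalization utilities
    that turn full fields into aligned training triplets, a from-scratch
    encoder-decoder convolutional network (U-Net) with skip connections
    trained by backpropagation (RcppArmadillo backend), and an evaluation
    protocol based on RMSE, piecewise PSNR and global SSIM on a [0,255]
    intensity scale with two-sample model comparison.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    tiff,
    png,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
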