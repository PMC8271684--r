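Package: oculocascade
Title: Coarse-to-Fine U-Net Cascade for Pupil and Iris Segmentation in
    Ocular Proton Therapy Surveillance Frames
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements a two-stage convolutional cascade that locates the
    eye in infrared surveillance frames and then segments the iris and pupil
    inside an automatically extracted region of interest. Provides a compact
    U-Net engine (batch-normalised 3x3 convolution blocks, leaky ReLU,
    2x2 up-convolution decoder with skip concatenation, sigmoid head) with
    the full training recipe (Adam, binary cross-entropy, paired geometric
    augmentation), morphological post-processing, overlap and contour
    metrics (Dice, Szymkiewicz-Simpson, IoU, Hausdorff), and a synthetic
    infrared eye-phantom generator with exact ground truth so the whole
    pipeline is testable without clinical video data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    EBImage,
    png,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    tiff
Config/testthat/edition: 3
RoxygenNote: 7.3.3
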