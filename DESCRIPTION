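Package: ghostgan
Title: Mask-Conditioned Generative Adversarial Networks with Ghost-Module
    Encoders for Medical Image Augmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for augmenting paired medical imaging datasets with a
    conditional generative adversarial network that maps binary lesion masks
    to synthetic scan images. The generator is a U-Net style encoder-decoder
    whose encoder can use ghost modules (a cheap depthwise expansion of a
    reduced set of intrinsic feature maps) to cut parameter counts, and is
    trained with a hybrid objective combining adversarial binary
    cross-entropy with a structural-similarity (SSIM) loss. Includes a
    synthetic tumor-phantom generator producing paired mask/scan PNG
    datasets, the resize/random-crop/normalize preprocessing pipeline,
    closed-form parameter-cost accounting for ghost versus standard
    convolutions, CPU training with full seed determinism and
    checkpointing, and SSIM-based evaluation of generated images. All
    numerical kernels (convolution, backpropagation, Adam) are implemented
    in C++ via 'RcppArmadillo' so the whole pipeline runs on a single CPU
    without any deep-learning framework.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    png,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
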