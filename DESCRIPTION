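Package: gfdnet
Title: Residual-Block CNN with a Categorical Generalized Focal Dice Loss for
    Dementia-Stage MRI Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Classifies 2D grayscale brain-MRI slices into four dementia
    severity stages (none, very mild, mild, moderate) with a compact
    residual-block convolutional network trained under a class-imbalance
    aware loss: the convex fusion of Focal Loss and Generalized Dice Loss.
    Provides the full chain as composable pieces: wavelet-based noise
    estimation fused with Non-Local Means denoising, CLAHE contrast
    enhancement, seeded affine augmentation, a from-scratch network with
    GroupNorm, Xavier initialization and ADAM training, stratified
    splits and k-fold cross-validation, confusion-matrix metrics, and a
    synthetic brain-phantom generator so everything is testable without
    any external image download.
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
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
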