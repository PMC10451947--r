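Package: ilcnn
Title: Lightweight Shift-Invariant Convolutional Networks for Finger-Vein Identification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a lightweight convolutional neural network for
    finger-vein identification built from diverse branch residual blocks:
    train-time multi-branch convolutions that fuse exactly into single
    convolutions for deployment (structural reparameterization), adaptive
    polyphase sampling for shift-robust downsampling, coordinate attention,
    and an elastic angular-margin softmax loss on L2-normalized embeddings.
    Includes a synthetic near-infrared vein-image generator, dataset
    splitting and ROI preprocessing, a seeded training loop with AdamW,
    identification evaluation by correct identification rate (CIR), and
    parameter/multiply-accumulate profiling. All network computation is
    double precision, with convolution kernels implemented via im2col and
    BLAS matrix multiplication in C++.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    png,
    yaml,
    EBImage
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
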