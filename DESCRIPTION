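Package: wormnet
Title: Multi-Order Convolutional Networks for Silkworm Re-Identification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Metric-learning toolkit for re-identification of elongated,
    arbitrarily posed animals such as silkworm larvae. Implements a
    residual convolutional backbone built from multi-order extraction
    blocks (parallel depth-wise convolutions at kernel sizes 3/5/7 over a
    1/4 channel split), a spatial feature-mask module, and a dual-branch
    (local/global) channel-interaction module, together with the
    triplet + center + identity training objective, identity-balanced PK
    batch sampling, cosine-similarity retrieval with mAP/CMC evaluation,
    top-k retrieval visualization, and a seed-deterministic synthetic
    worm-image generator producing Market1501-style train/gallery/query
    splits. Forward and backward passes are implemented natively
    (Rcpp/Armadillo convolution kernels, manual backpropagation, Adam),
    so the full pipeline runs on a single CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    grDevices,
    jsonlite,
    stats,
    utils,
    yaml,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
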