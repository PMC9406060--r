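Package: hvem
Title: Hierarchical Ventral-Stream Voxelwise Encoding Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voxelwise encoding models for human visual cortex fMRI built on a
    learnable Gabor convolutional network, with a two-stage hierarchical
    readout that re-uses the representation learned on a low-level visual
    area (V1/V2) to predict voxel activity in high-level areas (V4/LO),
    either from the predicted voxel space (voxel perspective) or from the
    convolutional feature space (feature perspective). Includes a
    weight-squaring backpropagation rule that emphasises predictive
    ("intimate") source voxels, a permutation-based validity threshold and
    model-comparison statistics (Top-K average accuracy, pairwise advantage
    with a coin-flip null, best-encoded-voxel proportions), a ridge
    regression control model over pluggable multi-layer image features, and
    a synthetic generator of vim-1-shaped datasets with a known V1-V2-V4-LO
    representational hierarchy and noise ceiling.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
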