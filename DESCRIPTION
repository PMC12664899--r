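Package: stgraft
Title: Transfer of Cell-Type Annotations from Single-Cell References to
    Spatial Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Transfers cell-type labels from an annotated single-cell RNA-seq
    reference to single-cell-resolution spatial transcriptomics data in three
    stages: a conditional negative-binomial variational autoencoder harmonizes
    batch effects between the two modalities in a shared latent space; a
    gradient-boosted tree classifier trained on the reference embedding emits a
    probabilistic teacher distribution for every spatial cell; and a dual
    autoencoder/graph-autoencoder fuses expression and spatial-neighborhood
    structure, distilling the teacher into a spatially coherent student
    classifier. Includes Gaussian-kernel k-nearest-neighbor spatial graphs,
    pseudo spatial-transcriptomics simulators for benchmarking, and the
    accuracy, weighted-F1, confusion-matrix and expression-profile correlation
    metrics used to evaluate annotation transfer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    ggplot2,
    jsonlite,
    methods,
    nnet,
    stats,
    utils,
    xgboost
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
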