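Package: scTypeCNN
Title: Multi-Scale Convolutional Cell-Type Annotation for Single-Cell
    RNA-Seq
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Supervised cell-type annotation for single-cell RNA-seq
    count matrices. Each cell's normalized expression profile is embedded
    as a square 2D gene image and passed through parallel multi-scale
    convolution/max-pooling branches; the resulting feature maps are
    concatenated with principal-component projections of the expression
    vector and classified by a multilayer perceptron trained with plain
    SGD on categorical cross-entropy. Query cells whose maximum softmax
    probability falls below a confidence threshold are rejected as
    "unknown", so cell types absent from the reference are not forced
    into known classes. Includes CPM/log preprocessing, gene filtering,
    stratified splitting, evaluation metrics (accuracy, macro F1,
    adjusted Rand index, ROC/PR curves), a negative-binomial synthetic
    data generator for desk-scale benchmarking, and end-to-end pipeline
    commands.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    Matrix,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: SingleCell, Transcriptomics, Classification, RNASeq
LinkingTo:
    Rcpp,
    RcppArmadillo
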