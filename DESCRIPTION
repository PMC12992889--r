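Package: pulmolayer
Title: Concentric Equal-Volume Lung Parcellation and MIP-Based CTPA Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for regional analysis of computed tomography pulmonary
    angiography (CTPA). Implements an iterative threshold-descent algorithm
    that orders lung voxels from the central vessels to the periphery and
    partitions each lung into four equal-volume concentric layers (Q1-Q4);
    a multi-angle masked maximum-intensity-projection (MIP) renderer; a
    frozen-encoder binary classifier with a trainable fully connected tail;
    and an evaluation harness with grouped repeated cross-validation,
    AUROC aggregation and masking-scheme comparison statistics. A synthetic
    CTPA phantom generator (ellipsoidal lung fields with branching vascular
    trees and injectable class-dependent signal) makes the whole pipeline
    testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    jsonlite,
    rlang,
    car
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
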