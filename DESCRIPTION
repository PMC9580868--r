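Package: voxelearn
Title: Accelerated Voxel Annotation for 3D Image Stacks by Sparse
    Stroke Tagging and Stacked Ensemble Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Headless pipeline for one-shot voxel classification of 3D
    image stacks (TIFF stacks, NIfTI volumes). Sparse stroke-based
    positive/negative voxel tagging, a 56-feature multi-scale 3D filter
    bank, five base classifiers (random forest, multi-layer perceptron,
    gradient boosting, support vector machine, naive Bayes) and a
    stacked strong learner, dense full-volume probability inference with
    blockwise tiling, transfer-function driven RGBA overlay compositing,
    Dice/RMSE evaluation against reference segmentations,
    impurity-based feature-importance reporting, an asynchronous
    learning-job service, and synthetic blob/tube phantoms with a stroke
    simulator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    jsonlite,
    tiff,
    RNifti,
    randomForest,
    xgboost,
    e1071,
    nnet,
    stats,
    utils,
    generics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
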