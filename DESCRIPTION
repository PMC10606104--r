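Package: histoclass
Title: Swarm-Optimized Feature Pipelines for Histopathological Lung Image Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end, fully seeded pipeline for binary classification of
    lung histopathology images (benign tissue versus adenocarcinoma). Images are
    denoised with a two-stage adaptive median filter, segmented with a modified
    kernel fuzzy C-means clustering that augments the pixel-to-centre distance
    with a spatially weighted fuzzy factor, and the segmented region-of-interest
    intensities are dimensionally reduced by particle swarm or grey wolf
    optimization over random-key subset encodings. Feature selection is done by
    symmetrized Kullback-Leibler divergence ranking of class-conditional
    intensity histograms or by invasive weed optimization over a Fisher-score
    criterion. Seven classifiers (RBF support vector machine, k-nearest
    neighbours, random forest, CART decision tree, softmax discriminant,
    multilayer perceptron, Bayesian linear discriminant) are trained against a
    numeric target encoding, with optional hyperparameter tuning by a
    finite-difference Adam loop and its controlled-randomization extension.
    Evaluation covers confusion-matrix metrics (accuracy, F1, MCC, Jaccard,
    g-mean, Cohen's kappa), stratified 10-fold cross-validation and a seeded
    synthetic tissue-image generator so the whole pipeline is testable without
    any external dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    tools,
    withr,
    jsonlite,
    e1071,
    ranger,
    rpart,
    png
Suggests:
    testthat (>= 3.0.0),
    optparse,
    tiff
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
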