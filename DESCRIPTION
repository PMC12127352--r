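Package: fascal
Title: Training-Free Layer Selection and Feature Calibration for Few-Shot
    Plant Disease Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for few-shot image classification on frozen backbone
    features, aimed at plant disease recognition. Implements the Feature
    Adaptation Score (FAS), a training-free statistic that ranks the
    intermediate layers of a feature extractor by their suitability for
    N-way-K-shot tasks, and Plant Disease Feature Calibration (PDFC), a
    non-parametric procedure that shifts support-set prototypes toward
    centroids built from a source-domain reference feature bank. Includes
    a full episode-based evaluation harness (prototype classifiers,
    accuracy and macro precision/recall/F1 over repeated runs),
    hyperparameter search by exhaustive grid and by Gaussian-process
    Bayesian optimization with Expected Improvement, labeled feature-bank
    storage (HDF5 and TSV), a deterministic toy backbone for image
    folders, and synthetic Gaussian feature generators with known ground
    truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lhs,
    optparse,
    png,
    purrr,
    readr,
    rhdf5,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
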