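Package: phantomnet
Title: Autoencoder Transfer Learning for Small 3D Medical-Image Datasets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for binary classification of small 3D grayscale medical-image
    datasets with convolutional transfer learning. Generates seeded synthetic
    brain-phantom volumes with Rician magnitude noise, applies percentile
    intensity windowing and training-set brightness normalization, expands
    training data with rigid (rotation + translation) augmentation, pretrains a
    3D convolutional autoencoder on patches from an unlabeled source corpus,
    transfers the encoder weights into a small 3D CNN classifier, and evaluates
    with leave-one-out cross-validation, repeated hyperparameter grid search,
    confidence-ranked triage curves, and paired transfer-versus-random
    initialization comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
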