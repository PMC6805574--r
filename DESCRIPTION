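Package: sepnet
Title: Compact Hybrid CNNs for Breast Histopathology with SEP-Block Channel Pruning
Version: 0.1.0
Authors@R: person("sepnet", "developers", role = c("aut", "cre"),
    email = "sepnet@example.org")
Description: Tools for building, compressing and evaluating compact hybrid
    convolutional neural networks for two-class breast histopathology image
    classification.  Provides a two-branch (global whole-image / local
    patch-voting) Inception-style network with squeeze-excitation blocks, a
    Squeeze-Excitation-Pruning (SEP) channel-pruning scheme with a geometric
    multi-loop schedule, multi-model bagging with softmax fusion, Reinhard
    lab-space stain color normalization, non-overlapping patch tiling and
    random augmentation, patient-aware data splitting, and patient-level /
    image-level evaluation metrics (PS, PL, IL, PPV, Cohen's kappa, F1, ROC).
    A synthetic histology-like cohort generator makes the whole pipeline
    testable at desk scale without any external dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    png,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jpeg
Config/testthat/edition: 3
RoxygenNote: 7.3.3
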