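Package: mrgadapt
Title: Adaptive-Strategy Prediction for MR-Guided Radiotherapy from
    Unsupervised Deformable Registration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts the per-fraction adaptive strategy in MR-guided
    adaptive radiotherapy of the prostate: adapt-to-position (ATP,
    repositioning only) versus adapt-to-shape (ATS, full online
    replanning). A 3D U-Net registration network is trained without
    supervision on paired reference-CT / daily-MR volumes using a
    differentiable mutual-information similarity loss with smoothness and
    L2 regularisation; its frozen encoder then feeds a small
    fully-connected head trained with binary cross-entropy to output the
    ATS probability. Includes a deformable multimodal phantom generator,
    NIfTI volume I/O and preprocessing (resampling, rigid pre-alignment,
    physical-unit mask expansion), a dose-volume-histogram rule engine
    producing dosimetric ground-truth labels, and registration /
    classification evaluation metrics (Dice, Hausdorff distance, ROC/AUC,
    confusion-matrix summaries, cohort aggregation).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: RNifti, jsonlite, yaml, Rcpp, stats, utils, graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), pROC, withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
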