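Package: nctstroke
Title: Three-Stage Subject-Level Cerebral Infarction Classification for Non-Contrast Head CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for subject-level classification of non-contrast head CT
    volumes for chronic cerebral infarction. Implements a three-stage
    pipeline: cranial-cavity segmentation with 2D or 3D encoder-decoder
    networks and boundary refinement, slice-wise stroke region proposals
    trained with a Dice loss and small-component removal, and a
    dual-resolution border-patch classifier trained with hard-negative
    mining whose patch probabilities are aggregated bag-of-local-features
    style into lesion and subject scores. Includes a synthetic head-CT
    phantom generator with ground-truth cavity and lesion masks, a compact
    CPU convolutional-network engine, and evaluation utilities (ROC/AUC,
    bootstrap confidence intervals, scanner- and age-stratified test sets,
    confusion matrices).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    oro.dicom
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
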