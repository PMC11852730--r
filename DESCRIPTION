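Package: paromics
Title: MRI Radiomics Pipeline for Discriminating Warthin's Tumors from
    Malignant Parotid Gland Tumors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end 3D MRI radiomics analysis for parotid gland tumors:
    preprocessing of paired T2-weighted and ADC volumes (bias-field
    correction, z-score normalization, outlier voxel removal, isotropic
    resampling, fixed-bin-width discretization), a wavelet plus
    Laplacian-of-Gaussian filter bank, extraction of 1037 shape,
    first-order and texture-matrix features per sequence, a four-stage
    feature-reduction cascade (ICC stability gate, Mann-Whitney with
    Benjamini-Hochberg correction, Spearman redundancy pruning, LASSO
    with cross-validation), a linear Radiomic Score, and ROC-based
    diagnostic reporting. Includes a synthetic cohort generator with
    class-separable texture structure so the whole pipeline is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    glmnet,
    jsonlite,
    rlang,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
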