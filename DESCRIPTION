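Package: fibroquant
Title: Quantitative Collagen Morphometry and Non-Invasive Test Evaluation
    for Liver Fibrosis Staging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantitative fibrosis assessment of two-channel
    multiphoton (second-harmonic generation / two-photon excitation
    fluorescence) liver biopsy images and for evaluating non-invasive
    fibrosis tests against histological staging. Includes a synthetic
    tissue-phantom and patient-cohort generator with exact ground truth,
    collagen and tissue segmentation, lumen detection and portal/central
    landmark classification, five-region lobular zonation, collagen string
    morphometry (named quantitative fibrosis parameters), a continuous
    qFibrosis score built by sequential feature selection and linear
    regression, serum score calculators (APRI, AAR, FIB-4, NFS, FAST,
    MAST), and a diagnostic layer with ROC/AUC, Youden and fixed
    sensitivity/specificity cutoffs, Spearman correlation matrices,
    stage-wise group tests, weighted kappa, and random-forest variable
    importance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    tiff,
    rpart,
    randomForest,
    generics
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
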