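Package: nodalrad
Title: Radiomics and Deep-Feature Classification of Thoracic Lymph Nodes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for classifying thoracic lymph nodes as
    PET-positive or PET-negative from contrast-enhanced CT. Implements
    hand-crafted first-order, shape and grey-level co-occurrence radiomics,
    transfer-learning style deep features pooled from a frozen convolutional
    backbone, and hybrid feature sets; elastic-net logistic regression and
    random-forest classifiers with PCA decorrelation and random hyperparameter
    search; patient-level repeated cross-validation with bootstrap bias
    correction of pooled out-of-fold predictions; and a calibration-aware
    evaluation suite (AUC, Brier score, scaled Brier score, Youden operating
    point, lowess calibration, paired bootstrap z-tests). Ships a synthetic
    CT lymph-node cohort generator so the whole experiment is reproducible
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    ranger,
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
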