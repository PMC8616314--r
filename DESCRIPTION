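Package: radfusion
Title: Multi-Sequence Radiomics Feature Fusion and Weighted Model Consensus
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for class-structured fusion of radiomics feature tables
    acquired from multiple MRI sequences. For each feature, the values
    observed across sequences form a small cross-modality matrix that is
    compressed through a between-class scatter whitening transform fitted
    on training data and reused unchanged at test time. A grid of feature
    selector and classifier combinations is screened by stratified
    cross-validation and the top-ranked models are merged into an
    accuracy-weighted soft-voting consensus. Also provides binary
    volume-of-interest mask utilities (Dice conformity, morphological
    union), evaluation harnesses (VOI and sequence-combination sweeps,
    reader comparison, top-feature frequency, class-mean thresholds), and
    a synthetic two-class multi-modality feature generator with
    closed-form single-feature discrimination for calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    RNifti,
    glmnet,
    e1071,
    ranger,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
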