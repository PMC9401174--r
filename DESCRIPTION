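Package: mrsiclass
Title: Single-Layer Convolutional Networks for MR Spectroscopic Imaging Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voxel-wise classification of MR spectroscopic imaging (MRSI) data
    with a single-layer convolutional neural network (SL-CNN) that fuses
    metabolite spectra with co-registered MR image patches, plus a
    stability-selection procedure that maps diagnostically relevant
    convolutional features back to spectral regions. Includes chemometric
    baselines (RBF support vector machines, PLS-DA, kernel PLS-DA with
    weighted multi-kernel fusion, multi-block PLS-DA), a leakage-safe
    leave-one-patient-out nested cross-validation harness with random grid
    search, Matthews correlation, ROC/AUC and DeLong AUC comparison, and a
    synthetic MRSI generator with class-dependent metabolite peaks and
    patient-level random effects for end-to-end testing without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
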