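Package: fusedr
Title: Dimensionality-Reduction-Based Multimodal Data Fusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A toolkit for fusing heterogeneous biomedical data modalities
    (imaging, omics, histology feature tables) through a common
    dimensionality-reduction workflow: knowledge representation (classifier
    decisions, kernels, low-dimensional embeddings via generalized
    eigendecomposition), resampling to generate ensembles of weak
    representations, knowledge fusion (direct, co-association matrix, and
    Procrustes-based structural fusion) with unweighted or learned modality
    weights, four preset fusion strategies, a bagged-tree evaluation harness
    with repeated grouped cross-validation and AUC, rank-based cross-strategy
    statistical testing, and a calibrated synthetic multimodal data generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    readr,
    rpart,
    vegan,
    MASS,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
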