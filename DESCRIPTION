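Package: gliotype
Title: Three-Class Glioblastoma Molecular Subtyping from Small Gene Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies glioblastoma specimens into the classical (CL),
    mesenchymal (MES) and proneural (PN) transcriptional subtypes from the
    expression of 5-20 marker genes. Covers the full path from raw qPCR CT
    tables or log-expression matrices through delta-CT normalisation against
    the geometric mean of reference genes, per-gene centering and
    standardisation, cross-platform reproducibility filtering, six-method
    feature ranking with mean-normalised cumulative aggregation, exhaustive
    fixed-size panel search, L1-penalised multinomial logistic (and linear
    SVM) classifiers with stratified cross-validation, to per-sample subtype
    probabilities and an evaluation battery (confusion/accuracy, one-vs-rest
    ROC/AUC, MDS centroid distances, bi-clustered heatmap ordering, subtype
    proportion tests). A synthetic cohort generator with planted
    subtype-specific expression blocks, platform distortions and CT-scale
    output makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    glmnet,
    e1071,
    MASS,
    jsonlite,
    yaml,
    withr,
    generics,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
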