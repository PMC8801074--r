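Package: mscpotency
Title: Morphology-Based Parallel Prediction of Mesenchymal Stromal Cell
    Potency and Growth
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Non-invasive prediction of mesenchymal stromal cell (MSC) lot
    quality from label-free time-lapse morphology. The package generates a
    fully synthetic but statistically calibrated benchmark of MSC lots
    (time-course single-cell area distributions, rendered phase-contrast-like
    images with ground-truth masks, and CFSE dilution co-culture readouts),
    segments cells and measures 16 morphological descriptors per cell,
    aggregates them into per-image mean/SD population-heterogeneity profiles,
    derives the two teacher signals (T-cell proliferation score from CFSE
    bimodality and fold-change growth rate from cell counts), and fits
    leave-lot-out cross-validated models (kNN, L1-penalised regression and
    random forests) for risk classification and growth-rate regression, with
    parameter-subset and time-window sweeps, LASSO selection reporting, PCA
    and average-linkage correlation clustering of lot structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    S4Vectors,
    SummarizedExperiment,
    data.table,
    glmnet,
    randomForest,
    mclust,
    EBImage,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown,
    pheatmap
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: CellBiology, Classification, Regression, Software
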