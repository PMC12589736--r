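Package: histofuse
Title: Histopathology Tile Classification with Active-Contour Segmentation,
    Fused Deep Features and Ant-Colony Feature Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for multiclass histopathology tile
    diagnosis: mean/Laplacian filter-fusion enhancement, region-based
    geometric active contour (Chan-Vese) segmentation with ROI export,
    pooled deep-feature extraction behind a pluggable extractor contract,
    serial feature fusion by concatenation, ant-colony-optimization feature
    subset selection, decision-tree and random-forest classification, and a
    macro-averaged one-vs-rest evaluation protocol with paired t-test model
    comparison. Ships a seeded synthetic tile generator with ground-truth
    masks so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    randomForest,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    MASS,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
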