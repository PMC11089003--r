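Package: mgstates
Title: Cell-State Analysis of Xenografted Human Microglia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the computational pipeline of xenografted-human-microglia
    single-cell studies: droplet quality control and hashtag demultiplexing,
    Wilcoxon rank-sum marker detection with detection-fraction and fold-change
    prefilters, binned-control gene-set module scoring, cross-dataset cell-state
    mapping by correlation of differential-expression log fold changes with
    conservative mouse-human ortholog resolution, per-mouse cell-state
    composition statistics, and a modified Sholl (concentric-annulus) radial
    intensity analysis of marker fluorescence around amyloid plaques. A
    synthetic-data module generates hashed droplet count matrices with planted
    cell states, ortholog tables and plaque images with known gradients, so
    every stage is testable against planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    methods,
    MASS,
    withr,
    EBImage,
    tiff,
    jsonlite,
    readr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
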