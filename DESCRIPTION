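Package: zonemap
Title: Spatial Immune Zonation Analysis for Segmented Cell Maps of Barrier Tissue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing immune zonation in segmented spatial maps of
    barrier tissues such as the human gingiva. Starting from per-cell tables
    produced by multiplexed imaging (marker intensities) or imaging-based
    spatial transcriptomics (transcript counts), the package provides
    Gaussian-mixture marker gating and rule-based cell phenotyping, k-nearest-
    neighbour niche detection, barrier-proximity zonation statistics relative
    to a reference epithelium, distance-binned stromal expression comparisons
    between conditions, ligand-receptor coexpression scoring within niches,
    and k-NN label transfer from a dissociated single-cell reference. A
    synthetic layered-mucosa generator plants known tissue architecture,
    expression gradients and condition effects so that every stage can be
    validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    mclust,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    mgcv,
    optparse
Config/testthat/edition: 3
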