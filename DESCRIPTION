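Package: canalseg
Title: Micro-CT-Guided Tooth and Root Canal Segmentation from CBCT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for building and evaluating micro-CT-guided root canal
    segmentation pipelines on cone-beam CT (CBCT) volumes. Provides a
    synthetic tooth phantom generator with known canal geometry and paired
    micro-CT/CBCT renderings, micro-CT thresholding and rigid ICP
    registration for transferring high-resolution ground-truth labels onto
    CBCT grids, a two-stage nested-U convolutional segmentation cascade
    (tooth, then root canal) trained slice-wise on axial planes, voxel
    overlap metrics (Dice, sensitivity, IoU) and signed surface-deviation
    analysis, voxel-size resampling experiments, and connected-component
    post-processing for false-positive removal.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
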