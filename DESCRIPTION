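Package: BoneAdapt
Title: Mechanoregulated Cortical Bone Adaptation from Micro-CT Images
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Predicts cortical bone adaptation in voxel images of the mouse
    tibia under physiological loading. Provides histogram-based segmentation
    with a transition zone, a matrix-free linear-elastic voxel (hexahedral)
    micro-finite-element solver with unit-load superposition, strain energy
    density and maximum principal strain stimulus fields, a node-centred bone
    remodelling unit (BRU) density update with tissue mineral density clamping,
    calibration of the remodelling rate and apposition limit from longitudinal
    image pairs via sectional volumetric second moments, densitometric and
    morphometric reporting over a 40-compartment atlas, longitudinal overlap
    and remodelling-site validation metrics, and a synthetic tibia-like
    phantom generator so the whole pipeline is testable without scan data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    tiff,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'BoneAdapt-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'voxel-image.R'
    'microfe.R'
    'remodelling.R'
    'morphometry.R'
    'metrics.R'
    'calibration.R'
    'phantom.R'
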