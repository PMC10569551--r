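Package: murivess
Title: Shallow 3D U-Net Segmentation of Murine Brain Vessels in Micro-MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fully automatic segmentation of blood vessels in micro-magnetic
    resonance imaging (uMRI) stacks of mouse brains. Implements the complete
    patch-based pipeline: brain-mask ROI extraction, padding, Gaussian
    smoothing and min-max normalisation; lossless 32x32x32 patch separation
    and reassembly; a shallow two-level 3D U-Net trained with binary focal
    loss under extreme foreground/background class imbalance; threshold and
    seeded region-growing post-processing; a multiscale Hessian (Frangi)
    vesselness baseline; confusion-matrix evaluation with accuracy, recall,
    precision and Dice; leave-one-out cross-validation; and a synthetic
    vascular phantom generator emulating the statistical structure of uMRI
    vessel data so the whole pipeline is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    tiff,
    RNifti,
    tibble,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
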