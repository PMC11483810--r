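Package: mesoreg
Title: Co-Registration Benchmarking for Vascular Photoacoustic Mesoscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for benchmarking 3D image co-registration of sparse
    vascular networks imaged with raster-scan photoacoustic mesoscopy.
    Provides a synthetic vascular-phantom generator with known ground-truth
    transforms and branch-point landmarks, the standard mesoscopy
    pre-processing chain (high-pass, adaptive Wiener, rolling-ball background
    removal, percentile clipping, slice-wise z-scoring), intensity-based
    affine registration by gradient ascent on mutual information or
    normalised cross-correlation, shape-based registration via point-to-plane
    iterative closest point and distance-transformed segmentations, a weakly
    supervised deformable registration network trained on a composite
    image/segmentation/bending-energy loss, a quality-metric suite (Dice,
    surface distances, mutual information, SSIM, target registration error),
    and paired non-parametric method comparison with Holm-Bonferroni
    correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    EBImage,
    jsonlite,
    tibble,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
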