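Package: flotr
Title: Fluorescence Laminar Optical Tomography Simulation and Reconstruction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates line-scan fluorescence laminar optical tomography
    (FLOT) acquisition of a fluorophore-filled capillary embedded in a
    scattering medium, reconstructs the three-dimensional fluorophore
    distribution through a Monte-Carlo-derived Born sensitivity matrix with
    Tikhonov regularization and L-curve parameter selection, and quantifies
    depth-dependent signal compensation against maximum intensity projection
    (MIP) imaging: voxel Monte Carlo photon transport with Henyey-Greenstein
    scattering and Fresnel boundaries, digital tissue phantoms, CCD noise
    models, depth-decay curves, 1/e depths, FWHM resolution profiles,
    exponential attenuation fits and N+3-sigma limits of detection.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    tiff,
    tibble,
    ggplot2,
    rlang,
    generics,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
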