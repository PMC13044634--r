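Package: corrspec
Title: Fluorescence and Raster Image Correlation Spectroscopy Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unified analysis of fluorescence correlation spectroscopy (FCS)
    photon traces and raster image correlation spectroscopy (RICS) image
    stacks. Provides FFT-based temporal and spatial autocorrelation
    estimators with image splitting and logarithmic downsampling,
    anisotropic single- and two-component diffusion models with triplet
    kinetics under Gaussian or experimentally measured 3D point spread
    functions, frequentist (nonlinear least squares) and Bayesian (nested
    sampling) fitting under uniform, weighted, and fully correlated error
    models with empirical lag covariance, evidence-based model comparison,
    diffusion-concentration pre-analysis screening, spatial parameter
    mapping, a Brownian-dynamics photon-emission simulator for validation,
    and HDF5/NetCDF persistence.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    minpack.lm,
    generics,
    rhdf5,
    ncdf4
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    tiff
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
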