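Package: sofiquant
Title: Quantitative Molecular Density Mapping and Cluster Analysis for
    SOFI Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for super-resolution optical fluctuation imaging (SOFI)
    of blinking fluorophores. Computes second- to fourth-order
    spatio-temporal cross-cumulant images from TIRF image sequences,
    inverts them into per-pixel molecular density maps using
    balanced-SOFI blinking statistics (molecular brightness and on-time
    ratio), and quantifies high-density regions (HDRs) by a
    threshold-free sweep over the full density range with automatic
    threshold selection. Includes fiducial-based drift correction with
    sub-pixel registration and a stochastic simulator of photoswitching
    fluorophores (Markov on/off kinetics, Gaussian PSF rendering,
    Poisson photoelectrons, EMCCD gain and Gaussian read noise) with
    known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    ggplot2,
    igraph,
    jsonlite,
    minpack.lm,
    rlang,
    stats,
    tibble,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
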