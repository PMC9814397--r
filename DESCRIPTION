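Package: holotrace
Title: Simulation, Reconstruction and 4D Particle Tracking for Lensless
    In-Line Holographic Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for point-source (lensless) digital in-line holographic
    microscopy of nano- to micro-scale particles. Simulates holograms of
    scenes of small scatterers with a first-Born point-scatterer model,
    forms contrast holograms, and numerically refocuses them at arbitrary
    depth with the Kirchhoff-Helmholtz transform (an exact direct-summation
    reference path and a fast gridded non-uniform FFT path). Includes
    closed-form optical metrology (numerical aperture, lateral and depth
    resolution limits, phase-shift / optical-path / refractive-index
    relations), crosscut profiles and full-width-at-half-maximum sizing,
    depth autofocus to sub-nanometre grids, 3D particle detection with
    dimension statistics, and 4D (x, y, z, t) trajectory recovery from
    hologram time series by consecutive-frame subtraction, fixed-plane
    reconstruction and nearest-neighbour track linking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    png,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tiff,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
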