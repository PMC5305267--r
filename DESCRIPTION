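Package: polartension
Title: Mechano-Chemical Simulation of Cell Polarization Under Membrane Tension
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates cell polarization as a mass-conserved, bistable
    (wave-pinning) reaction-diffusion system of active Rac-GTP, inactive
    Rac-GDP and F-actin, coupled to a spatially homogeneous membrane
    tension that acts as a fast global inhibitor of actin polymerization.
    The cell is embedded in a regular periodic grid through a phase-field
    indicator whose diffuse layer represents the membrane, and the coupled
    equations are advanced with a stabilized exponential Fourier-spectral
    scheme.  Includes stimulus protocols (graded gradients, local random
    patches, random switching schedules), polarity analytics, and drivers
    for in-silico experiments: polarization-threshold curves, perturbation
    stability, micropipette aspiration-release, and severing of a tethered
    pseudopod-neck-body cell, plus an alternative flat 2D model in which
    tension throttles actin growth through a Brownian-ratchet factor.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    yaml,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
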