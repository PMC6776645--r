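Package: cubofuse
Title: Single-Particle Analysis of Lipid Nanoparticle Fusion with Supported Bilayers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the fusion of cubosome lipid nanocarriers
    with supported lipid bilayers from total internal reflection fluorescence
    (TIRF) image stacks. Implements a finite-source two-dimensional lipid
    diffusion model that predicts a t^(-1/6) decay of the peak fluorescence of
    a fusing particle, together with the numerical oracles behind it (explicit
    2-D diffusion solver, point-source Green's function, footprint growth).
    Provides a seeded synthetic TIRF movie generator with bilayer patterns,
    Brownian particles, scripted fusion events and camera noise; Crocker-Grier
    style spot detection, trajectory linking, mean-squared-displacement
    diffusion estimation and Stokes-Einstein sizing; fusion-event segmentation,
    power-law intensity-decay fitting and fusion-time estimation; and
    supported-bilayer formation kinetics (surface coverage with error-function
    fits, domain counting, nucleation-and-growth simulation). A small pipeline
    driver ties the stages together around TIFF, CSV, JSON and YAML files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    deSolve,
    minpack.lm,
    tiff,
    yaml,
    jsonlite,
    Rcpp,
    EBImage
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
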