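Package: vesselgrow
Title: Hemodynamics-Driven Growth and Remodeling of Aortic Aneurysms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing ascending aortic aneurysm progression with a
    stress-homeostasis kinematic growth-and-remodeling model. Provides
    triangulated tube-mesh input/output with harmonic (Laplace) axial and
    circumferential surface coordinates, ring-based radius and length
    measurements, a lumped three-element Windkessel and thin-wall stress
    surrogate for the hemodynamic load, anisotropic growth-law integration,
    Levenberg-Marquardt fitting of growth time constants to longitudinal
    geometry, validation metrics against later time points, Tobit censored
    regression of fitted constants against lifespan, and a synthetic
    longitudinal-cohort generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    minpack.lm,
    survival
Config/testthat/edition: 3
RoxygenNote: 7.3.3
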