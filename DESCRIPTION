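Package: callusmod
Title: Collagen Fiber Orientation Analysis and Stiffening Model for
    Distraction Osteogenesis Calluses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies collagen-fiber organization in confocal z-stacks of
    regenerating bone callus (sum and maximum projections, gradient
    structure-tensor orientation fields, orientation distributions and their
    standard deviation, mean-gray-value densitometry) and models the apparent
    axial stiffening of the fibrous callus during limb distraction as the
    product of an orientation coefficient obtained by unit-sphere averaging
    of fiber stress, a density coefficient quadratic in relative fiber
    density, and a maturation coefficient driven by a first-order collagen
    maturation equation. Includes a seeded synthetic-data generator for
    fibered image stacks and forward-simulated stiffness series, bounded
    least-squares fitting of the model parameters, and an end-to-end
    pipeline with plain-text configuration and outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
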