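Package: kleaf
Title: Leaf Hydraulic Conductance from Evaporative Flux Balance Logs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Processing chain for the evaporative flux method (EFM) of leaf
    hydraulic conductance (K_leaf) estimation: reads raw balance weight logs,
    converts cumulative reservoir weight to area-normalized transpirational
    flow with background-evaporation correction, identifies steady-state flow
    by penalized dynamic-programming piecewise-linear segmentation and a
    trailing-window slope t-test, computes K_leaf with water-viscosity
    normalization to 25 degrees C, provides hydrostatic-pressure and
    sensitivity diagnostics, writes a standardized unit-annotated metadata
    report alongside the raw flow table, and includes a synthetic trace
    generator with analytic ground truth so the whole pipeline can be
    validated without instruments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
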