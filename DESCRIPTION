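Package: ptxpulse
Title: Joint Design of Parallel-Transmit RF and Gradient Pulses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design tools for parallel-transmit (pTx) excitation at ultra-high
    field MRI. Jointly optimizes every sample of the multi-channel complex RF
    voltage waveforms and the three gradient waveforms by adaptive gradient
    descent through differentiable forward models: a full Bloch simulator
    (hard-pulse rotation per raster step) and a small-tip-angle spatial-domain
    model. A composite cost balances flip-angle error against hardware limits
    (per-channel voltage, gradient amplitude, slew rate, zero-edge samples),
    average pulse power, and maximum local SAR predicted from Virtual
    Observation Point matrices. Includes a 3-kT-point magnitude-least-squares
    benchmark designer, slab-selective and large-flip-angle design recipes,
    synthetic field-map and VOP generators for testing, MATLAB-container and
    ini-style pulse file I/O, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    withr
Config/testthat/edition: 3
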