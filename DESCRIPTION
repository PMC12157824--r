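Package: radmotion
Title: Markerless Motion Classification from CW-Radar Micro-Doppler Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for marker-trained, markerless
    radar motion classification. Synthesizes sinusoidal marker micro-motions
    for exercise-like motion classes, simulates the complex baseband signal of
    a continuous-wave radar from marker ranges, extracts per-marker maximum
    circular cross-correlation amplitude features against marker-derived basis
    functions, compresses them with principal component analysis and
    classifies with a nearest-neighbour rule. Includes an experiment harness
    for SNR and dimensionality grids, training segmentation sweeps and
    robustness studies (time scaling, two-motion mixtures and amplitude/phase
    perturbations).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
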