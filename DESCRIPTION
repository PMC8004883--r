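Package: psprmap
Title: Phase-to-Refractive-Index Mapping for Phase-Sensitive SPR Biosensing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts phase-sensitive surface plasmon resonance (pSPR)
    phasograms into reproducible refractive-index sensorgrams. A five-layer
    Fresnel reflectivity model (prism/chromium/gold/probe/buffer, Kretschmann
    configuration) is fitted to sensor calibration data by seeded Bayesian
    optimization, meta-modeled as three segmented cubic polynomials, and used
    as an invertible phase-to-refractive-index mapping. Also provides a
    simulator for the phase-modulation homodyne interferometer with
    generalized lock-in (GLIA) phase demodulation, Langmuir 1:1 binding
    kinetics fits on converted sensorgrams, synthetic chip and calibration
    generators, and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    grDevices,
    lattice,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
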