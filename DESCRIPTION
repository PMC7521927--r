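Package: vestcoding
Title: Spike-Train Variability and Coding Strategy in Central Vestibular Neurons
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for studying how resting-discharge variability
    shapes the coding strategy of central vestibular neurons. Provides a
    synthetic-cohort generator (naturalistic head-velocity stimuli,
    gamma-renewal resting discharges, linear-nonlinear cascade responses,
    model eye movements), multitaper spectral estimation for spike trains and
    traces with Poisson surrogate confidence bands, temporal-whitening and
    coherence-based information measures, optimal linear (Wiener) stimulus
    reconstruction with coding fraction, linear-nonlinear response-spectrum
    prediction, and a vestibulo-ocular reflex transfer-function model with a
    spectral matching index.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
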