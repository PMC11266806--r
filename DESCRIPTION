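Package: impedcyto
Title: Virtual Multi-Frequency Impedance Cytometry for Label-Free Rare-Cell
    Detection
Version: 0.1.0
Authors@R:
    person("Devin", "Okafor", email = "d.okafor@example.org",
           role = c("aut", "cre"))
Description: A forward simulator and analysis pipeline for differential
    multi-frequency impedance flow cytometry. Models single cells with the
    single-shell dielectric description and computes the complex
    Clausius-Mossotti factor, simulates cell transits through a four-pair
    differential electrode array (including an optional carrier-level lock-in
    demodulation path), implements the signal-processing chain (detrend,
    filter, event detection, peak extraction, electrical diameter and opacity
    features), trains a small one-dimensional convolutional network with
    channel attention on 100-by-6 signal fragments to discriminate white
    blood cells from tumor cells, emulates inertial-microfluidic
    separation/concentration stages as calibrated stochastic capture, solves
    laminar flow-divider hydraulics, and reports sample-level circulating
    tumor cell counts with a configurable diagnosis rule.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
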