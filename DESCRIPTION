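Package: exostrength
Title: Lower-Limb Strength Estimation from Hip-Exoskeleton Resistance-Exercise Performance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for estimating lower-limb muscular strength from
    resistance exercise performed with a hip-joint exoskeleton. Generates synthetic
    cohorts of joint-torque and surface-EMG exercise sessions with known ground
    truth, processes the raw signals (notch and band-pass filtering, MVIC
    normalization, repetition-peak detection), extracts per-exercise performance
    metrics (repetition counts, initial speed, constant-speed zone, sEMG amplitude
    and iEMG deltas), constructs a z-score composite strength index from vertical
    jump, one-repetition-maximum and isometric measurements, and fits statistically
    screened multivariable regression models with effect-size, post-hoc power and
    bootstrap-with-noise validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    pracma,
    lmtest,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
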