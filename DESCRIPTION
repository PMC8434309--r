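Package: ecgsync
Title: Prospective ECG-Gated Trigger Simulation and Evaluation
Version: 0.1.0
Authors@R:
    person("ecgsync", "developers", email = "ecgsync@example.org",
           role = c("aut", "cre"))
Description: Discrete-time implementation of a real-time ECG-to-TTL
    synchronization algorithm for prospective cardiac gating: adaptive
    decaying-threshold R-wave detection on a finite-difference derivative
    estimate, phase-offset trigger scheduling, and fixed-width TTL pulse
    generation.  Ships a seeded synthetic ECG generator (Gaussian P-QRS-T
    morphology, baseline wander, motion artifacts), an ex-post ideal-trigger
    oracle, an evaluation harness reporting false-positive/false-negative
    rates and trigger timing offsets, plus readers and writers for
    delimited-text signal formats and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
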