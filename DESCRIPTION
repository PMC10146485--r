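Package: homeostat
Title: Integral Feedback Controller Motifs and Vertebrate Photoreceptor
    Adaptation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the eight basic integral-feedback controller motifs
    (inflow/outflow, activation/derepression, with zero-order or antithetic
    integral control) under step and background perturbations, extracts
    response metrics (maximum excursion, time-to-peak, resetting period),
    locates just-noticeable-difference threshold stimuli and fits
    Weber/Stevens psychophysical laws, and implements a three-feedback-loop
    kinetic model of vertebrate photoreceptor adaptation (cGMP, cytosolic
    calcium and potassium, with CNG channel, guanylate cyclase, PDE and
    NCKX kinetics) including loop dissection, calcium-leak calibration and
    closed-form cGMP set-point. Includes a seeded synthetic dose-response
    generator for Hill-fit parameter recovery studies and bundled presets
    reproducing the package's reference experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
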