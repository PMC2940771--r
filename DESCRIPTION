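Package: sigspec
Title: Specificity and Fidelity in Interconnected Cell Signaling Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Steady-state models of two signaling pathways that share an
    intermediate component, with linear, hyperbolic or ultrasensitive (Hill)
    activation. Computes output-specificity and input-fidelity indicators
    (S_X, S_Y, F_X, F_Y) and their composites (MS, MF, MFMS), models three
    insulating mechanisms (cross-pathway inhibition, combinatorial signaling,
    scaffolding/compartmentalization) with a common cross-regulatory term,
    evaluates closed-form MFMS bounds and their sharpness, analyzes
    derivative-based strategies for increasing ultrasensitivity, and runs
    seeded Monte-Carlo parameter sweeps with percentile summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
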