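Package: scgnet
Title: Neural Network Surrogate Solutions of a Compartmental Language-Learning Model
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Solves a three-compartment model of language acquisition (unknown,
    familiar, mastered proportions) with an exact matrix-exponential solution
    and a fourth-order Adams-Bashforth-Moulton predictor-corrector, then trains
    a small log-sigmoid feedforward network with Moller's scaled conjugate
    gradient algorithm to emulate the reference trajectories. Provides seeded
    train/validation/test splitting, multi-restart training with early
    stopping, and the standard fitting diagnostics: per-split mean squared
    error, absolute-error curves, signed-error histograms and regression R
    squared. Everything is deterministic given a seed; no external data are
    required.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    deSolve,
    Matrix,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
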