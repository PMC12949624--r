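Package: sprkin
Title: Kinetic and Equilibrium Analysis of SPR Biosensor Sensorgrams
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulation and analysis of surface plasmon resonance (SPR)
    biosensor experiments for weakly binding, mechanistically complex
    analytes such as disordered peptides. Provides forward simulation of
    sensorgrams under competing binding schemes (1:1 Langmuir, two-state
    induced fit, heterogeneous ligand, and a fuzzy multi-mode ensemble with
    interconversion), a synthetic-experiment generator with realistic
    instrument artifacts, double-referencing preprocessing, global kinetic
    regression, pseudo-steady-state affinity and binding-efficiency
    estimation, corrected-AIC model comparison, contact-time invariance
    diagnostics for mechanism discrimination, thermal-shift melting-point
    estimation, and average-mass bookkeeping for terminally modified and
    lactam-stapled peptides.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    minpack.lm,
    stats,
    graphics,
    grDevices,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
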