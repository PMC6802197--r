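Package: intadyn
Title: Single-Molecule and Ensemble Analysis of Intasome-Target DNA Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for single-molecule magnetic-tweezers and
    atomic-force-microscopy studies of retroviral intasome interactions with
    supercoiled target DNA. Provides closed-form DNA mechanics (supercoiling,
    bending and interface free energies, Bell-model force dependence,
    tip-convolution geometry), seeded simulators of extension traces, rupture
    experiments, ensemble integration kinetics and AFM particle tables,
    an unbiased chi-square step finder with counter-fit quality control,
    exponential dwell-time maximum-likelihood estimation with chi-square
    confidence intervals, kernel-density and periodicity analysis of
    supercoil-release step sizes, Bell-model force spectroscopy fits, a
    global error-weighted kinetic model of ensemble strand transfer, and
    topology and geometry statistics for AFM particle measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    deSolve,
    minpack.lm,
    zoo,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    Matrix
Config/testthat/edition: 3
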