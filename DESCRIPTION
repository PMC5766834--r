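Package: gluflux
Title: Kinetic Modelling and Trajectory Analysis of Glutamate Binding to
    Ionotropic Receptors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying agonist binding and gating of ionotropic
    glutamate receptors. Simulates macroscopic receptor currents from a
    multi-state Markov gating scheme driven by realistic agonist
    concentration jumps, and analyses current traces (sigmoid rise times,
    monoexponential decay fits, Hill dose-response fits, Hodgkin-Huxley
    recovery fits, errors-in-variables straight-line fits). Also computes
    three-dimensional potentials of mean force from ligand-coordinate
    trajectories by Boltzmann inversion of hard-sphere occupancy densities,
    with block-averaged uncertainties, metastable-site extraction and
    cleft-closure order parameters, and estimates association rate
    constants from detected binding events. Seeded Brownian-dynamics and
    noisy-trace generators provide ground-truth-known inputs for every
    analysis stage.
License: MIT
Encoding: UTF-8
Imports:
    deSolve,
    minpack.lm,
    Matrix,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
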