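Package: gliosim
Title: Stochastic Simulation of Calcium Signaling and Gliotransmitter
    Release in an Astrocytic Perisynaptic Process
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Biophysical simulator of a single astrocytic perisynaptic
    compartment: glutamate- and DHPG-driven IP3 production, stochastic
    Markov gating of a small IP3 receptor cluster on the endoplasmic
    reticulum, SERCA/PMCA pumps, kinetic calcium buffers, and a dual
    calcium-sensor (synaptotagmin-4/synaptotagmin-7) vesicle release
    machine with docked and mobile pools, kiss-and-run and full-fusion
    exocytosis, endocytosis and recycling. Includes parameter transforms
    for amyloid-beta perturbations of mGluR and PMCA function, calcium
    event detection and kinetics, percentage-response quantification,
    Pinsky-Rinzel event synchrony, joint-PSTH cross-correlation, Hill
    dose-response fitting, and a seeded batch runner with CSV/JSON export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    minpack.lm,
    jsonlite,
    graphics,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    optparse
Config/testthat/edition: 3
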