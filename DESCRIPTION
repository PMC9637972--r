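Package: spidec
Title: Binodals and Interfacial Tension from Simulations of Spinodal Decomposition
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Coarse-grained simulation and analysis toolkit for computing
    phase-coexistence densities (binodals) and interfacial tension of
    phase-separating systems from spontaneous spinodal decomposition.
    Provides Langevin molecular-dynamics and Metropolis Monte Carlo engines
    for Lennard-Jones particles, bead-spring Lennard-Jones chains,
    hydrophobic-polar chains and tetrahedral Kern-Frenkel patchy particles;
    density-profile and interface (tanh) fitting, slab counting and
    phase-separation time scales, morphology classification of the dense
    phase, Kirkwood-Buff interfacial tension, critical-point fitting, and
    van der Waals / Flory-Huggins theory curves.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
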