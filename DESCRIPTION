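Package: crxn
Title: Reactive Coarse-Grained Simulation of Macrocyclization in Peptide Condensates
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A reduced reactive coarse-grained Langevin-dynamics simulator and
    analysis pipeline for studying disulfide macrocyclization of bifunctional
    monomers inside liquid-liquid phase-separating peptide condensates.
    Simulates sticker-spacer peptides with a pH-dependent terminal-charge
    toggle, bifunctional dithiol monomers with stochastic bond
    formation/breakage, and optional explicit solvent. Provides ring-size
    census and consumption kinetics from the disulfide bond graph, slab
    density profiles with tanh interface fits, simulated partition
    coefficients, droplet clustering, incoherent intermediate scattering
    functions with AIC-based exponential model selection, umbrella sampling
    with WHAM free-energy profiles, and the experimental partition-assay
    arithmetic (calibration curves, mass-balance concentrations, and transfer
    free energies).
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    minpack.lm,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
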