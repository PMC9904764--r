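Package: cgphos
Title: Coarse-Grained Simulation of Phospho-Regulated IDR Conformations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Residue-level (alpha-carbon) coarse-grained molecular dynamics
    for intrinsically disordered regions (IDRs) and their phospho-regulated
    conformational changes. Implements the hydropathy-scale (HPS,
    Ashbaugh-Hatch) and Kim-Hummer model D pair potentials with
    Debye-Hueckel screened electrostatics, phosphoserine/phosphothreonine
    charge states, harmonic backbone bonds, rigid folded domains integrated
    as quaternion rigid bodies, and a BAOAB Langevin thermostat. Ships the
    analysis pipeline for radius of gyration, inter-IDR center-of-mass
    separation, contact maps, autocorrelation-based equilibration trimming,
    five-block error estimates, charge-composition diagnostics, and
    coil-globule temperature scans, plus synthetic-data generators so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    Biostrings,
    bio3d
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
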