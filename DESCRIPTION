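Package: trem2flex
Title: Trajectory Analysis of TREM2 CDR2 Flexibility and TREM2-ApoE Interfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-processing toolkit for molecular dynamics trajectories of
    the TREM2 immunoglobulin-like ectodomain and its complexes with ApoE
    isoforms. Implements loop-distance metrics (Loop 1/Loop 2), standard
    deviation threshold conformational clustering into Clusters A/B/C with
    medoid representative selection, Kabsch superposition with per-frame RMSD
    and per-residue RMSF, backbone phi/psi torsions with Ramachandran
    secondary-structure counting, residue-residue minimum-distance contact
    maps with a CDR-versus-hinge docking-model selection filter, and
    cluster-resolved interaction-energy statistics (two-way ANOVA,
    Tukey-Kramer comparisons, occupancy-weighted ensemble energies, rank
    concordance with experimental affinities). Ships synthetic-data
    generators that emulate two-state loop dynamics, docked poses with
    controlled interface contacts, and cluster-structured energy tables, so
    the full pipeline is testable end to end without the original
    trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    car,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
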