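Package: mdligand
Title: Comparative Trajectory Descriptors and Interaction Fingerprints for
    Protein-Ligand Complexes
Version: 0.1.0
Authors@R: person("Maintainer", "mdligand", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Desk-scale analysis pipeline for comparing two protein-ligand
    systems from multi-model PDB trajectories: Kabsch superposition and
    iteratively pruned-pair RMSD, per-frame RMSD / per-residue RMSF / radius
    of gyration with summaries, three-class residue flexibility
    classification and sliding-window differential-flexibility detection,
    geometric interaction fingerprints (hydrogen bonds, salt bridges,
    pi-stacking, hydrophobic contacts) with per-contact persistence,
    MM/PBSA-style energy component bookkeeping, and a combinatorial R-group
    library stage with drug-likeness rule filtering. A seeded synthetic-data
    module generates every fixture the pipeline needs (toy complexes,
    fluctuation trajectories with prescribed per-residue amplitudes,
    planted-interaction snapshots, energy series), replacing docking and MD
    engines so the whole analysis runs in seconds.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
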