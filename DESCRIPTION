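Package: ppitriage
Title: Computational Triage of Peptidomimetic Protein-Protein Interaction Inhibitors
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A toolkit for structure-based triage of peptide-like
    protein-protein interaction inhibitors. Provides multi-model PDB
    input/output, backbone torsion and Kabsch superposition kernels,
    interface contact-conservation mapping across receptor-effector
    complexes, a post-docking pose filtering cascade (Ramachandran
    compliance, peptide-bond planarity, intramolecular steric clashes,
    docking-energy cut), trajectory-based ligand binding-stability
    classification, an in-house Shrake-Rupley solvent-accessible
    surface area routine with conformer-ensemble polar-area averaging
    for passive-permeability prediction, mixed-solvent probe-occupancy
    hotspot mapping, and seeded synthetic-fixture generators so the
    whole cascade is testable offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
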