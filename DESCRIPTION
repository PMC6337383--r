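Package: dynophoreR
Title: Docking-Pose Clustering, Dynamic Pharmacophores and Virtual-Screening Analytics
Version: 0.1.0
Authors@R: person("Maintainer", "Dev", email = "dev@example.org", role = c("aut", "cre"))
Description: Tools for the bespoke computational stages of a structure-based
    inhibitor-discovery campaign against a membrane transporter: common-scaffold
    clustering of docking-pose ensembles, static and dynamic protein-ligand
    interaction fingerprints, per-frame structure-based pharmacophore perception
    with excluded-volume spheres, occupancy profiling and model clustering with
    representative-model selection, pharmacophore screening of multi-conformer
    libraries with one allowed feature omission, consensus scoring, enrichment
    statistics (ROC/AUC/RIE) and ligand-efficiency metrics. Docking and molecular
    dynamics engines are consumed as file inputs (SDF, PDB, CSV); seeded synthetic
    generators emulate their outputs so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
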