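Package: cavitrack
Title: Ligand Translocation, Solvation and Binding-Pocket Analysis for
    Molecular Dynamics Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analyses the entry of small-molecule ligands into buried
    receptor binding sites from molecular dynamics trajectories:
    reference-site mapping by Kabsch superposition, per-frame
    ligand-to-site distance series, segmentation of the ingress into
    metastable states (contact, entry, vestibule, binding), entry-event
    counting over trajectory cohorts, first-solvation-shell water
    counting normalised to a bulk reference, per-residue contact
    frequency statistics, representative-frame selection by k-means,
    grid-based cavity detection with volume and polarity scoring,
    simplified hydrophobic and electrostatic surface-complementarity
    scores for pose ranking, and binding-pocket sequence-conservation
    statistics from multiple sequence alignments. Includes a synthetic
    data generator that plants translocation trajectories, hydration
    boxes, alignments and complementarity test complexes with exact
    machine-readable ground truth, so every stage is testable without
    running molecular dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    seqinr,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    bio3d,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
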