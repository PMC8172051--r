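Package: idrbind
Title: Trajectory Analysis of Disordered-Tail Receptor-Ligand Binding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for coarse-grain molecular dynamics ensembles of
    a membrane receptor with an intrinsically disordered N-terminal tail and a
    diffusing protein ligand. Computes residue-wise minimum-distance contact
    probability maps, detects stable ligand-binding events and aligns replicate
    ensembles at the time of binding, clusters tail conformers with the
    GROMOS (Daura) algorithm, builds 2D population-density landscapes over
    backbone RMSD and an inter-residue side-chain distance, fingerprints
    ligand binding modes by structural elements, and quantifies chemical shift
    perturbations (weighted amide 1H/15N) and their concordance with contact
    profiles. Includes a synthetic-ensemble generator with planted, recorded
    ground truth so every pipeline stage has a parameter-recovery test.
License: MIT
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
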