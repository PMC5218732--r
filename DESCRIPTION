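Package: hydroqsar
Title: Hydrophobicity-Density-Field 3D-QSAR for Estrogen Receptor Alpha Ligands
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Structure-based scoring of estrogen receptor alpha (ERa)
    ligand binding. Evaluates an empirical hydrophobicity density field on
    the ligand solvent-accessible surface, integrates hydrophobic contact
    with pocket residues into a log PC descriptor, detects geometric
    protein-ligand interaction features (hydrogen bonds, salt bridge,
    T-shaped pi-stacking, A-ring arrangement, His524 conformational class),
    assembles them into a 3D interaction fingerprint, and predicts relative
    binding affinity with a published linear QSAR model. Also provides
    GA-MLR model retraining with leave-one-out validation, consensus
    clustering and rescoring of externally generated docking poses, and a
    synthetic fixture generator so the whole pipeline is testable without
    external structures.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    ChemmineR,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
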