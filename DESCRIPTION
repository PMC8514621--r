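Package: zern3d
Title: 3D Zernike Descriptors for Antibody-Antigen Surface Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Rotation-invariant 3D Zernike descriptors of molecular surface
    patches, applied to antibody-antigen interfaces. Builds solvent-accessible
    surface point clouds with per-residue electrostatic values from PQR/PDB
    structures, extracts antibody CDR patches, paratope shells, native epitopes
    and SASA-matched decoy epitopes, voxelizes shape and signed electrostatic
    channels onto the unit ball, expands them into rotation-invariant Zernike
    invariants, and provides similarity and complementarity metrics, a
    nearest-neighbour antigen-type classifier, and decoy-discrimination ROC
    analysis, together with synthetic-surface generators for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
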