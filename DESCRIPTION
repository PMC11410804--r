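Package: symlattice
Title: Symmetry-Based Assembly of Protein 2D Lattices from Predicted Oligomers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects rotational symmetry axes in predicted protein oligomer
    models, filters them by confidence score, steric clashes and
    intermolecular beta-strand content, clusters them by binding interface
    with the Louvain method, and superposes pairs of axes into a repeating
    two-dimensional lattice (wallpaper groups p1, p2, p3, p4, p6) or a
    curved capsid tile. Emits the primitive unit cell with symmetry
    operations as mmCIF. Includes a structure-aware domain separator, the
    five-subchain truncation scheme, and a synthetic fixture generator that
    builds pseudo-protein oligomers and planted lattices with known ground
    truth so the whole pipeline can be exercised without a structure
    predictor.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
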