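Package: qdock
Title: Quantum Search for Protein-Ligand Docking Sites on the Lattice
    Interaction Space
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies and ranks candidate protein-ligand docking sites on
    the lattice interaction-space model with a simulated quantum pipeline.
    Each interaction site carries a hydrophobic and a hydrogen-bonding
    strength; sites are encoded either as two-qubit binary labels (for
    search) or as amplitude-embedded superposition states (for evaluation).
    A Grover search restricted to the subspace spanned by the distinct
    ligand-sized windows of the protein, driven by a segmentation, shift and
    recursive-bisection controller, localizes candidate sites; candidates
    are then ranked by the quantum Euclidean distance between amplitude
    encodings, estimated with a SWAP test. Both an exact statevector backend
    and a seeded finite-shot sampling backend are provided, together with a
    synthetic-data generator with planted docking sites, CSV/JSON/YAML
    input-output and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
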