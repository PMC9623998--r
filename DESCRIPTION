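Package: denshot
Title: Densest-Subgraph Prediction of Protein-Protein Interaction Hot Spots
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts binding hot-spot residues in protein-protein
    interfaces by extracting high-density vertex-induced subgraphs from
    residue interaction networks. Builds contact networks from PDB/mmCIF
    structures (inter-chain atomic contacts within the sum of van der
    Waals radii plus one water diameter), and implements a family of
    exact linear- and integer-linear-programming extractors: the densest
    subgraph (DS), all minimal densest subgraphs (Min-DS), the unique
    maximal densest subgraph (Max-DS), and minimal sub-densest subgraphs
    peeled down to a density tolerance (Min-SDS). Includes alanine-scanning
    ddG labelling from SKEMPI-style affinity tables, precision/recall/F-beta
    evaluation, deterministic synthetic fixtures, and a command-line
    front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    bio3d,
    jsonlite,
    tibble,
    stats,
    utils
Suggests:
    boot,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
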