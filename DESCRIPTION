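Package: focuslib
Title: Focused Combinatorial Library Design for Enzyme Active-Site Redesign
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Desk-scale workflow that turns an aminoacyl-tRNA-synthetase
    active site and a noncanonical amino acid into a focused combinatorial
    mutant library: ligand conformer ensembles diversified over side-chain
    dihedral angles, geometric hydrogen-bond matching of contact residues,
    simulated-annealing active-site redesign under a simplified three-term
    score, filtering and substrate-orientation clustering of design models,
    sequence-profile curation, and exact library diversity and
    transformant-coverage statistics.  Ships synthetic fixture generators
    with planted ground truth so every stage is testable without external
    structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    Biostrings,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
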