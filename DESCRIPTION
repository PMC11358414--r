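Package: consnet
Title: Conservation and Contact-Network Analysis of Receptor Activation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Evolutionary-structural analysis of G-protein-coupled receptor
    activation, centred on the class F (Frizzled/Smoothened) family.
    Implements per-position ortholog conservation scoring with
    BLOSUM-similarity grouping, cross-paralog conservation fractions and
    Shannon-entropy sequence divergence, residue-residue contact score
    (RRCS) networks and their active-minus-inactive difference, mapping of
    conservation and contact changes onto structures (water-adjacent
    residues, conserved surface patches, sterol contact sites), and
    structure and trajectory geometry: helix kink angles, transmembrane
    helix opening between states, chi1/chi2 rotamer series, distance
    series with two-state classification, and water-occupancy voxel
    grids. Includes deterministic seeded generators for synthetic
    alignments, helix bundles and frame series with planted ground truth,
    so every stage of the pipeline is testable offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    igraph,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
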