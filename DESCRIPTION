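Package: pathmat
Title: Adjacency-Matrix Views of Binary Protein Relations in Pathways
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Parses extended SIF (simple interaction format) files carrying
    the eight Pathway Commons binary relation types, together with a
    two-column TSV dialect describing nested protein complexes.  Computes a
    set-based dissimilarity between proteins, a greedy similarity ordering
    for matrix seriation, and a single-pass leader-algorithm grouping of
    structurally equivalent proteins; summarises relation-type frequencies
    as an area-proportional Venn circle layout; derives complex-hierarchy
    listings, arc-diagram geometry and matrix membership overlays; and
    renders adjacency-matrix, Venn and arc-diagram scenes as static SVG with
    an optional bifocal lens.  A synthetic fixture generator with planted
    structure supports testing without external pathway exports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Matrix,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
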