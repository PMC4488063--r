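Package: topocomp
Title: Topological Comparison of Large Sets of Phylogenetic Trees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing large sets of phylogenetic trees on a shared
    taxon set: split- and clade-based topological distances (local Jaccard-type
    distances and global distances normalized by the run-wide element universe),
    sensitivity (clade stability) analysis across analytical conditions with
    SVG "navajo rug" plots, rogue/wildcard taxon detection by leave-one-out
    average matching split distance, and parsimony-based synapomorphy
    compilation and categorization (unambiguous changes classified as unique
    non-homoplastic, unique homoplastic, or non-unique homoplastic). Includes
    readers for Newick and TNT-style parenthetical tree files and a simplified
    NEXUS character matrix, a seeded synthetic-data generator, and a
    configuration-driven command-line front end.
License: MIT
Encoding: UTF-8
Imports:
    ape,
    phytools,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    phangorn,
    xml2,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
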