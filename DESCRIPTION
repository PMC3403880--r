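Package: moleculecloud
Title: Molecule Cloud Diagrams of Large Compound Collections
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reduces collections of molecules to their most frequent
    scaffolds (Murcko frameworks) and major chains, and renders them as a
    compact cloud diagram in which image size encodes log-frequency, in
    analogy with word clouds for text. Implements a two-pass layout engine
    (greedy placement on a dense grid minimizing an overlap score, followed
    by iterative hill-climbing refinement with corner repulsion), color
    coding by bioactivity ratio or dominant target class, and a pluggable
    depiction-provider interface so any cheminformatics toolkit can supply
    SMILES parsing and 2D drawing. Ships an OpenBabel-backed provider, a
    synthetic power-law fixture generator, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ChemmineOB,
    ChemmineR,
    igraph,
    jsonlite,
    Rcpp,
    grDevices,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
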