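Package: edtgraph
Title: Equal-Divergence-Time Graphs and Time-Consistent Reconciliation Scenarios
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for reasoning about the relative timing of gene and species
    divergences in evolutionary scenarios.  A time-consistent reconciliation of
    a dated gene tree with a dated species tree partitions all pairs of genes
    into three vertex-colored graphs: the later- (LDT), equal- (EDT) and
    prior-divergence-time (PDT) graphs.  The package computes this 3-partition
    from a scenario, extracts the informative and forbidden rooted triples it
    implies for the gene and species trees, decides in polynomial time whether
    a colored 3-partition is explainable by a relaxed scenario, and constructs
    explaining relaxed and restricted scenarios.  It further recognizes PDT
    graphs and HGT-free EDT graphs, provides a small-instance exhaustive EDT
    recognizer, computes the weak/strict (quasi-)orthology graphs and the
    symmetrized Fitch graph, and ships a synthetic scenario simulator together
    with plain-text graph/scenario formats and a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
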