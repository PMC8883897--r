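Package: pathcomp
Title: Low-Cost Pairwise Comparison of Metabolic Pathway Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares metabolic pathways represented as directed graphs of
    metabolite labels. Pathway graphs are linearized by breadth-first
    traversal from an origin node and the resulting label sequences are
    aligned with global, local and semi-global dynamic programming,
    reporting absolute scores (matches, mismatches and gaps under a linear
    scoring scheme) and relative scores normalized by sequence length. A
    complementary edge-level method, Differentiation by Pairs, lists the
    reactions unique to each pathway and summarizes them as a numerical
    difference fraction. Includes readers and writers for two JSON pathway
    dialects (adjacency dictionaries and reaction substrate/product
    layouts), candidate-selection rules based on origin and destiny nodes,
    pairwise structural features with factor bucketing, a factorial
    experiment planner, a seeded synthetic pathway generator, and a batch
    comparison pipeline with CSV/JSON reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
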