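Package: wastrid
Title: Species Trees from Weighted Average Internode Distances
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Species tree estimation from collections of unrooted gene
    trees under incomplete lineage sorting, using support- or
    branch-length-weighted average internode distance matrices. Missing
    entries arising from incomplete gene trees are imputed by a two-stage
    UPGMA*-based completion, and the species tree is inferred by a
    balanced minimum evolution search (greedy insertion followed by NNI
    and optional SPR local moves). Includes Robinson-Foulds evaluation
    utilities and a multispecies coalescent simulator with gene-tree
    error and missing-data models for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    igraph,
    optparse,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
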