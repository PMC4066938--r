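Package: niblpa
Title: Node-Influence-Based Label Propagation for Community Detection
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects communities (modules) in undirected networks, such as
    protein-interaction graphs, with the node-influence-based label
    propagation algorithm (NIBLPA): asynchronous label propagation with a
    fixed node-update order derived from a k-shell-weighted node-influence
    centrality, and a label-influence rule replacing random tie-breaking.
    Includes the classic LPA and the k-shell-ordered KBLPA baselines,
    partition-quality metrics (Newman modularity, pair-based F-measure,
    normalized mutual information), Clique-Ring and planted-partition
    benchmark generators, readers and writers for edge lists and membership
    tables, and a small benchmarking harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
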