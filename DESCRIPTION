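Package: dgmod
Title: Community Detection by Greedy Modularity with Disassembly Exploration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Modularity-based community detection for undirected, unweighted
    networks such as protein-protein interaction and metabolic networks.
    Implements Clauset-Newman-Moore greedy modularity agglomeration with
    incremental modularity-gain bookkeeping, augmented by stochastic
    exploration moves that disassemble nodes or whole communities chosen by
    quality criteria (weakness, embeddedness, triad participation, internal
    edge density, conductance) to escape local optima. Includes partition
    quality metrics, normalized mutual information for comparing partitions,
    readers and writers for edge-list and GML graphs and membership tables, a
    seeded planted-partition benchmark generator with power-law degree and
    community-size distributions, strategy-grid experiment drivers, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
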