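Package: modgraph
Title: Modular Random Graphs with Tunable Community Structure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates undirected, simple, connected random graphs with a
    specified degree distribution (Poisson, geometric, power-law, or an
    explicit degree sequence), a specified number and size distribution of
    communities, and a tunable strength of community structure measured by
    Newman modularity Q. Degree and within-degree sequences are sampled
    under Handshake, Erdos-Gallai and Chungphaisan realizability criteria;
    edges are wired by (modified) Havel-Hakimi construction and randomized
    by degree-preserving double-edge swaps subject to class constraints.
    Includes structural metrics (assortativity, clustering, path length),
    partition-comparison metrics (Jaccard similarity, variation of
    information), configuration-model counterparts, extraction of a
    generation recipe from an empirical network for null-model ensembles,
    and file readers/writers for edge lists, partitions, GML and GraphML.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    optparse,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
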