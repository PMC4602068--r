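Package: setweaver
Title: Combinatorial Integration and Analysis of Heterogeneous Gene Set Collections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Harmonizes heterogeneous, cross-species gene sets into a bipartite
    genes-by-gene-sets graph and analyzes them with set algebra, Jaccard
    similarity, exact hypergeometric overlap tests, a hierarchical intersection
    DAG built from maximal bicliques, guilt-by-association gene ranking, and
    degree-based hub-gene discovery. Includes readers and writers for GMT and
    long-form TSV gene sets, homology cluster tables, graph exports (GraphML,
    DOT, JSON), a builder for literature-term gene sets with a minimum-evidence
    filter, and a seeded synthetic-data generator with planted structure so
    every tool can be exercised offline against a known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
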