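Package: aimirna
Title: miRNA Target-Set Enrichment for Amelogenesis Imperfecta Gene Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links a curated registry of genes mutated in amelogenesis
    imperfecta to candidate regulatory microRNAs. Provides loaders and
    classification tallies for the curated gene registry, aggregation of
    miRNA-target predictions from multiple sources, one-sided exact-test
    (hypergeometric / Fisher) over-representation analysis with
    Benjamini-Hochberg false-discovery-rate control, inversion of printed
    enrichment tables to recover unstated background parameters, bipartite
    miRNA-gene and merged protein-protein interaction networks with
    Cytoscape-compatible export, and a seeded synthetic-data generator for
    type-I error, power, and parameter-recovery validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    vctrs,
    ggplot2,
    igraph,
    jsonlite,
    generics,
    withr,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
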