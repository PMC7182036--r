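Package: elin
Title: Early Life Immune Network Assembly, Denoising and Marker Prioritization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Assembles literature-derived causal statements into six
    period-specific multilayer immune networks covering human early life
    (three gestational trimesters, birth, newborn and infant periods),
    denoises gene-gene edges against a reference human functional
    association table, enriches the networks with gene-process,
    gene-disease and bioprocess-endpoint annotations, infers cross-layer
    edges from gene-set overlap (hypergeometric test with
    Benjamini-Hochberg control and Jaccard weights), prioritizes nodes
    with PageRank over the full heterogeneous topology, and compares
    top-ranked gene sets across periods. Ships a synthetic-data generator
    with planted hub genes so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    igraph,
    jsonlite,
    Matrix,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
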