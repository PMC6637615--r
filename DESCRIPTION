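Package: metregr
Title: Mechanistic Path Explanations in Combined Metabolic and Regulatory Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Finds and ranks weighted mechanistic paths of influence linking
    perturbed (condition) and changed (effect) genes, proteins and metabolites
    in a combined metabolic and transcriptional-regulatory network. Edge costs
    penalise unspecific hubs (common metabolites, global regulators) so that
    lightest-weight paths favour specific, biologically interpretable routes.
    Supports a directed mode (condition and effect sets given) and an
    undirected mode (effects only), in which candidate common influencers are
    scored and a greedy covering set is posited as conditions. Results are
    partitioned into metabolic temporary pathways and regulatory components
    and exported as styled DOT, GraphML or JSON explanation graphs. Includes a
    seeded synthetic-network generator emulating pathway/genome-database
    structure so every stage is testable without a curated database.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    glue,
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
    optparse,
    stringr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
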