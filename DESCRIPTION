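Package: comorbnet
Title: Phenotypic Disease Networks, Interactome Backbones and miRNA
    Bipartite Analysis for Type 1 Diabetes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds phenotypic disease networks from inpatient claims using
    the phi-correlation comorbidity statistic, thresholds them to the top
    fraction of links, categorizes diseases into ICD-9-CM chapters and
    compares category composition between strata with two-sample proportion
    tests. Computes node centralities and global topology of protein
    interaction graphs, extracts high-betweenness backbones, classifies
    nodes into the date-hub / party-hub / nonhub-bottleneck taxonomy, and
    analyses bipartite protein-miRNA targeting networks and pathway
    membership overlap. Includes a synthetic-data generator (correlated
    Bernoulli claims cohorts, modular graphs with planted connectors,
    random bipartite networks) so the full pipeline is testable without
    access to restricted claims data.
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
    stringr,
    tibble,
    tools,
    tidyr,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
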