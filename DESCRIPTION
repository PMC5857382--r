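Package: sporegcn
Title: Dynamic Sporulation Gene Co-Expression Network Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstruction and analysis of staged gene co-expression
    networks for sporulating bacteria. Estimates sparse partial
    correlations (SPACE-style joint regression or exact inversion),
    prunes them to an undirected weighted network, detects and curates
    random-walk (walktrap) modules, characterises topology (truncated
    power-law degree distribution, clustering coefficients, random
    baselines), calls differentially expressed genes across sporulation
    phase contrasts, extracts regulon sub-networks, performs
    hypergeometric gene-set enrichment, and intersects two networks to
    find conserved modules. A synthetic-data generator with planted
    modules, regulons and differentially expressed genes provides ground
    truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    mclust,
    fgsea,
    withr,
    Rcpp,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
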