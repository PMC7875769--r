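Package: enhancermap
Title: Active-Enhancer Calling, Enhancer Modules and GWAS Enrichment on
    Epigenomic Compendia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale implementation of a regulatory-genomics analysis
    chain for large epigenomic compendia: calling active enhancers from
    DNase hypersensitive sites, chromatin-state segmentations and H3K27ac
    signal; clustering enhancers into activity modules with a k-centroids
    algorithm under the Jaccard distance; predicting enhancer-gene links
    with gradient-boosted trees on expression-activity correlations;
    pruning GWAS catalogs and testing flat, module and tree-based
    hypergeometric enrichments with Benjamini-Hochberg correction and
    empirical shuffle FDR; partitioning traits across tissues with
    fixed-marginal permutation tests and trait-trait networks; and quality
    control of imputed signal tracks including sample- and antibody-swap
    detection. A seeded synthetic-compendium generator with planted ground
    truth (modules, links, trait-tissue associations, swaps) makes every
    stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    tools,
    jsonlite,
    xgboost,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    pROC,
    igraph,
    yaml
Config/testthat/edition: 3
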