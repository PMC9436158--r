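Package: phenonet
Title: Phenotype Networks from Shared GWAS Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds trait-trait phenotype networks from GWAS-Catalog-style
    association tables: traits are nodes, and two traits are linked when they
    share genetic variants, with edge weights given by the Jaccard index of
    their variant sets and edge significance assessed by a one-sided Fisher's
    exact (hypergeometric enrichment) test with Benjamini-Hochberg false
    discovery rate control. Provides trait filtering against ontology
    categories and keyword rules, Louvain community detection with a
    degree-preserving rewiring significance test, network summaries (degrees,
    log-binned degree distributions, eigenvector centrality, per-variant edge
    counts), differential subnetworks attributable to a focal study source,
    ancestry-stratified network comparison via binary neighborhood-vector
    correlations, and a synthetic catalog generator with planted ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    yaml,
    mclust,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
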