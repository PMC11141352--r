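Package: MicrobeNet
Title: Microbial Co-Occurrence Networks and Community Statistics from
    Taxon Abundance Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds signed microbial co-occurrence networks from
    taxon-by-sample abundance tables via Spearman correlation with
    Benjamini-Hochberg false discovery rate control, detects modules,
    classifies node roles on the Zi-Pi (within-module connectivity /
    among-module connectivity) plane to identify keystone taxa, and
    summarises network topology. Also provides alpha-diversity
    estimators (Chao1, Shannon, Pielou), Bray-Curtis dissimilarity with
    PERMANOVA and Mantel permutation tests, non-metric multidimensional
    scaling with Kruskal stress, variance-inflation-factor screening of
    covariates, a synthetic community generator with planted correlation
    modules and known keystones for end-to-end validation, and a
    config-driven pipeline runner.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    igraph,
    vegan,
    jsonlite,
    yaml,
    xml2
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
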