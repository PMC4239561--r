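Package: fracres
Title: Fractionation Resistance of Duplicate Genes After Whole-Genome Doubling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantifies how gene functional category and expression level
    predict retention of duplicate genes after whole-genome multiplication.
    Computes per-homology-set fractionation-resistance levels (F = N + 1 over
    the species still retaining duplicates), propagates Gene Ontology
    annotation up the term hierarchy and across homology-set members, reduces
    RPKM expression matrices to per-gene maxima with a top-percentile filter
    and log-scale binning, and estimates category-membership and expression
    trends across resistance levels by regression, classifying categories as
    fractionation-resistant or fractionation-prone. A forward simulator of
    category- and expression-dependent duplicate retention supports
    validation and power analysis, and a deterministic end-to-end pipeline
    writes tidy result tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    lmtest,
    sandwich,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
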