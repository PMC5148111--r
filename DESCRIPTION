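Package: rifnet
Title: Differential Co-Expression Networks and Regulatory Impact Factors
    for 2x2 Factorial Expression Designs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for discovering candidate transcriptional regulators from
    expression profiles collected under a two-breed by two-altitude migrant
    design. Implements detection-call filtering and quantile normalization,
    per-probe two-way factorial ANOVA with Benjamini-Hochberg FDR control,
    phenotype impact factor (PIF) scoring, PCIT (partial correlation and
    information theory) co-expression edge filtering, regulatory impact
    factor (RIF1/RIF2) scoring with z-standardization, extraction of
    top-regulator subnetworks for Cytoscape, hypergeometric
    over-representation with fold enrichment, and a seeded synthetic-data
    generator that plants differential expression and differentially wired
    regulators for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    limma,
    igraph,
    jsonlite,
    yaml
Suggests:
    car,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
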