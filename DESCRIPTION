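Package: orthoMapper
Title: Topological Mapper Analysis of Cross-Species Orthogroup Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for mapping the shape of cross-species plant gene
    expression with topological data analysis. Assembles orthogroup-by-sample
    TPM matrices from OrthoFinder-style orthogroup tables and per-species
    expression tables, constructs tissue and stress lens functions as
    residual norms from a linear model of reference (leaf or healthy)
    samples, builds Mapper graphs as the one-dimensional nerve of a
    DBSCAN-clustered interval cover, simplifies them by greedy Jaccard
    agglomeration, ranks orthogroups by lens correlation, and tests
    gene-set enrichment with exact binomial and hypergeometric tests.
    Includes a synthetic expression-matrix generator with planted tissue
    and stress signal for end-to-end validation, and a factor-balance
    audit with seeded downsampling of over-represented factor combinations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
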