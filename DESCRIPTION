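Package: villagefactor
Title: Multicellular Gene-Expression Program Discovery from Pooled-Donor
    Single-Nucleus RNA-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing pooled-donor ("village") single-nucleus
    RNA-seq experiments, in which tissue from around twenty donors is
    processed as one library and donors are resolved computationally from
    transcribed SNPs.  The package covers the full desk-scale pipeline:
    genotype-likelihood donor demultiplexing with cross-donor doublet
    detection; paralog-aware joint UMI quantification of high-homology gene
    families (metagenes); Pearson-residual normalisation, per-cell-type
    pseudobulk aggregation and robust donor outlier exclusion via conformity
    scores and modified z-scores; cross-cell-type latent factor inference by
    variational Bayes with automatic relevance determination; covariate
    association statistics; preranked gene-set enrichment with permutation
    p-values and leading-edge extraction; and within-cell-type consensus
    non-negative matrix factorisation with stability-based model selection.
    A seeded synthetic-village generator with planted latent programs,
    doublets, paralog families and aberrant donors makes every stage
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    jsonlite,
    stats,
    utils,
    graphics,
    cluster,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea
Config/testthat/edition: 3
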