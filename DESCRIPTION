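Package: senmetflux
Title: Time-Resolved Multi-Omics Analysis of Senescence Metabolic Reprogramming
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for time-course metabolome and transcriptome studies of
    cellular senescence across multiple stress inducers. Implements a
    benchmark of batch-correction methods scored by relative standard
    deviation, repeatability and the Bhattacharyya distance; per-batch
    differential calling (one-way ANOVA with Benjamini-Hochberg correction)
    and metabolite-ratio fold-change signatures; weighted-correlation
    coexpression module detection with topological overlap and eigenprofile
    merging; cross-inducer gene-metabolite Spearman correlation networks with
    betweenness-centrality hub ranking; hypergeometric over-representation
    and pre-ranked permutation GSEA. A synthetic-data generator emulating the
    multi-batch, multi-timepoint design with planted modules, hub metabolites
    and batch effects makes every stage testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    limma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    igraph,
    sva,
    fgsea,
    withr
Config/testthat/edition: 3
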