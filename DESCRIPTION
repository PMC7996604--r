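Package: metabopair
Title: Paired Plasma-CSF Targeted Metabolomics Correlation Analysis
Version: 0.1.0
Authors@R:
    person("Pkg", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for matched-biofluid targeted metabolomics:
    reading and filtering MRM peak-area tables, replicate averaging and
    log transformation, per-metabolite robust (Huber IRLS) regression of
    cerebrospinal-fluid on plasma levels with weighted correlation
    coefficients, group-wise correlation-loss classification, pairwise
    metabolite correlation networks with degree-corrected stochastic
    block-model partitioning and percentile subgraphs, hypergeometric
    pathway overrepresentation with Benjamini-Hochberg FDR, and PCA /
    UMAP / OPLS-DA profile projections. Includes a synthetic-data
    generator with planted correlation structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    data.table,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    uwot,
    optparse
Config/testthat/edition: 3
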