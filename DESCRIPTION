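Package: cytodict
Title: Cytokine Stimulation Screen Analysis for Multi-Donor PBMC Single-Cell Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for large multi-donor cytokine stimulation
    screens of peripheral blood mononuclear cells profiled by single-cell
    RNA sequencing. Provides pseudobulk differential expression with
    per-control-well robustness filtering, response-magnitude and
    tissue-specificity metrics, donor heterogeneity and outlier
    diagnostics, ligand-receptor communication scoring, cytokine
    response-similarity grouping, significance calling for latent
    cytokine-induced gene programs, and a preranked permutation
    enrichment engine for detecting cytokine responses and differential
    cell-cell communication in query datasets. Includes a synthetic-data
    generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    yaml,
    mclust,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
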