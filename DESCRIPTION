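Package: exprevo
Title: Evolution of Gene Expression Presence/Absence on Phylogenies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative transcriptomics of gene expression
    presence/absence. Binarizes cross-species TPM expression tables at a
    mixture-model-calibrated cutoff, fits a two-state general
    time-reversible substitution model with free-rate among-gene rate
    heterogeneity on a fixed species phylogeny, reconstructs marginal
    ancestral expression states by empirical Bayes, traces
    lineage-specific expression gains and losses at a posterior
    probability threshold, embeds extant and ancestral transcriptomes by
    classical multidimensional scaling with K-means grouping, and tests
    recruited gene sets for cell-type enrichment in single-cell data.
    Includes simulators that generate every pipeline input with recorded
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    jsonlite,
    Matrix,
    stats,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
LinkingTo:
    Rcpp
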