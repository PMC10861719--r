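Package: scDimorph
Title: Sex-Stratified Single-Cell Differential Expression and Boolean
    Regulatory Network Perturbation Analysis
Version: 0.1.0
Authors@R:
    person("Maintainer", "scDimorph", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for sex-stratified single-cell
    transcriptomics of transgenic-versus-wildtype mouse designs: quality
    control and centered log-ratio normalization, shared-nearest-neighbor
    clustering with silhouette-based model selection and marker-based
    cell-type annotation, per-stratum Poisson generalized linear model
    differential expression with Bonferroni adjustment and classification
    of genes into sex-neutral, sex-specific and sex-dimorphic patterns,
    hypergeometric over-representation analysis of GMT gene-set
    collections, genetic-algorithm selection of Boolean-consistent
    genotype-specific regulatory subnetworks from a signed prior-knowledge
    interaction network (with inference of unknown edge signs), and
    in-silico perturbation ranking of upstream regulators by the number of
    downstream genes reverted toward the control state. A synthetic-data
    module generates count matrices, marker and pathway gene sets, and
    ground-truth signed networks with planted effects so that every stage
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
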