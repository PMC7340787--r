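Package: coexppi
Title: Weighted Co-Expression Modules Projected onto Protein Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A desk-scale pipeline for finding candidate drug targets from
    tumor expression cohorts: builds a weighted gene co-expression network
    (soft-threshold adjacency, scale-free fit, topological overlap,
    adaptive dendrogram cutting, module eigengenes, module-trait
    statistics), projects the module partition onto a confidence-filtered
    protein-protein interaction network to isolate a trait-associated
    critical module and rank its members by degree, and validates
    candidates with Wilcoxon differential expression, Kaplan-Meier /
    log-rank survival splits, hypergeometric over-representation, and a
    running-sum gene-set enrichment statistic with permutation null. A
    synthetic-data module with planted latent-factor modules, a
    recurrence-like binary trait, expression-dependent survival, a modular
    PPI graph and matched gene sets provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    stats,
    survival,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
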