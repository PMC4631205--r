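Package: gutflux
Title: Constraint-Based Analysis of Gut Microbiota Effects on Host Metabolism
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constraint-based metabolic modelling toolkit for studying how the
    gut microbiota reshapes host metabolism. Implements flux balance analysis,
    parsimonious FBA and flux variability analysis on genome-scale metabolic
    models (SBML with flux-balance-constraints annotations or a plain-text toy
    format); the RMetD procedure for turning relative differential gene
    expression into condition-specific flux bounds and comparing predicted
    secretion of objective products; artificial-centering hit-and-run sampling
    of the feasible flux space with concordance calls for transcriptionally
    regulated reactions; Hamming-distance comparison of model ensembles with
    heterogeneity and core/unique statistics; a diet-partitioned two-species
    gut community simulation with cross-feeding; reporter-metabolite scoring of
    gene-level statistics on the network; and seeded synthetic-data generators
    for every input class so the whole pipeline is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
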