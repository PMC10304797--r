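Package: phona
Title: Phenotype-OTU Network Analysis for Amplicon Microbiome Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds phenotype-anchored microbial association networks
    (PhONA) from OTU count tables. Infers compositionally corrected
    OTU-OTU correlations with SparCC and bootstrap edge significance,
    selects phenotype-predictive OTUs by L1-regularised regression with
    repeated cross-validation, signs their phenotype links with a reduced
    generalized linear model, and merges both into one graph with
    simulated-annealing module detection and within-module degree /
    participation-coefficient node roles. Also provides the supporting
    community statistics (alpha diversity, Bray-Curtis + PERMANOVA,
    negative-binomial differential abundance with Benjamini-Hochberg
    control) and a synthetic compositional data generator for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    igraph,
    jsonlite,
    MASS,
    Rcpp,
    stats,
    utils,
    vegan,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    biomformat,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
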