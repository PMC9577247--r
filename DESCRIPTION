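Package: nanoherit
Title: Variance Partitioning, Heritability and Selection Analysis for
    Biomass-Derived Material Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical-genetics style analysis of hierarchically structured
    biomass-material experiments, built around a sorghum-to-nanopaper study
    design (varieties, plant sections nested in variety, homogenisation energy
    levels, nanopaper duplicates and strip replicates). Provides expected-mean-
    squares and EM-REML variance component estimation for the random-effects
    model, factor "heritability" shares and rankings, agglomerative hierarchical
    clustering of samples and characterisation metrics with Newick export, and
    selection-gradient / predicted-response analysis (multivariate breeder's
    equation) against tunable material-quality definitions. Includes a
    synthetic-data generator reproducing the experimental design so the whole
    pipeline is testable without the original dataset.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape,
    lme4,
    mclust
Config/testthat/edition: 3
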