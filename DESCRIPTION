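Package: gpfsel
Title: Genomic Prediction with Feature Selection and Leakage-Aware
    Cross-Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for SNP-based genomic prediction of quantitative traits:
    G-BLUP (REML mixed model on a VanRaden genomic relationship matrix),
    Bayes C (Gibbs sampling with an estimated exclusion proportion), and a
    fixed hit-list QTL regression model, together with a GRAMMAR two-step
    association scan, one unsupervised and four supervised SNP feature
    selection algorithms (P-value ranking, median-interval pruning,
    interval-conditional and haplotype-block-conditional P-values), and a
    cross-validation harness that makes feature-selection leakage an
    explicit, audited choice.  A synthetic cohort simulator with linkage
    disequilibrium blocks, population stratification, and sib-family
    relatedness provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
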