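Package: coabnet
Title: Coabundance Networks, Differential Edges, and Mediation Linkages for
    Longitudinal Microbiome Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Downstream inference for longitudinal, grouped microbiome
    studies profiled as feature-abundance tables: compositional transforms
    (CLR, rank-based inverse normal) and diversity summaries; SparCC basis
    correlations with permutation significance, computed per subgroup;
    cross-subgroup edge heterogeneity by Cochran's Q with inverse-variance
    weights and Benjamini-Hochberg control; group-specific edge calls by an
    interquartile-range fence rule with Kleinberg hub scoring; stratified
    rank-based differential-feature testing with Dunn post hoc contrasts;
    within-subject delta associations between microbial and trait changes
    screened by Spearman correlation; and metabolite-mediated linkage
    inference by quasi-Bayesian causal mediation on linear models. A
    synthetic-data generator with recorded ground truth (log-normal basis,
    multinomial reads, planted edges and mediation chains) makes every
    stage testable without access to the original sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    Matrix,
    igraph,
    vegan
Suggests:
    testthat (>= 3.0.0),
    withr,
    metafor,
    jsonlite
Config/testthat/edition: 3
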