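Package: canalex
Title: Gene Expression Variability and Inheritance Patterns in Reciprocal Crosses
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies gene expression variability (canalization) from
    replicated RNA-seq count matrices with the Local Coefficient of Variation
    (LCV), a sliding-window percentile of the coefficient of variation among
    genes of similar mean expression. Clusters genes by their variability
    profiles across cross-type by time-point groups (k-means with silhouette
    verification), fits per-cluster Bayesian linear models by Gibbs sampling
    to obtain posterior modes and 95% highest-posterior-density intervals,
    and classifies inheritance patterns of both expression variability and
    mean expression (maternal, morph-biased, intermediate, over-/underdominant,
    transgressive) in a two-morph reciprocal-cross design. Includes a
    negative-binomial Wald test for differential expression with
    Benjamini-Hochberg correction, proportion tests with Bonferroni control,
    and a negative-binomial simulator that plants known inheritance patterns
    for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    MASS,
    cluster,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
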