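Package: gruyere
Title: Genome-Wide Rare Variant Enrichment Evaluation with Learned
    Functional Annotation Weights
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A Bayesian rare-variant association test for case-control
    traits that learns trait-specific functional-annotation weights
    jointly across genes and then tests each gene with a likelihood-ratio
    test. Per-variant effects are a deterministic function of a scalar
    gene effect, a Beta(1,25) minor-allele-frequency weight, and a
    simplex of genome-wide annotation importance weights estimated by
    stochastic variational inference. Includes construction of
    cell-type-specific non-coding variant sets from Activity-by-Contact
    enhancer-gene predictions, annotation preprocessing (min-max scaling,
    rank-1 non-negative matrix factorization of annotation groups, splice
    delta-score maxima, assay delta-score aggregation), a synthetic
    cohort generator and parameter-recovery simulation study, Cauchy
    (ACAT) omnibus p-value combination, and prediction metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    methods,
    vcfR,
    IRanges,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
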