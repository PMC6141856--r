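Package: coexhub
Title: Weighted Gene Co-Expression Networks, Module Detection and Hub-Gene
    Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Constructs soft-thresholded weighted gene co-expression networks
    from log-scale expression matrices, computes the topological overlap
    measure (TOM), detects co-expression modules by average-linkage
    clustering of the TOM dissimilarity with a minimum-size branch cut,
    relates module eigengenes to clinical traits, screens hub genes by
    module membership and trait significance, and validates candidates with
    Kaplan-Meier/log-rank survival analysis, ROC curves and group
    comparisons. Includes a seeded latent-factor simulator that plants
    co-expression modules, an ordinal grade trait, expression-dependent
    survival times and tumor/normal mean shifts, with ground truth for
    recovery testing, plus hypergeometric over-representation analysis over
    GMT gene sets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    survival,
    pROC,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
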