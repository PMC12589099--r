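Package: pmcov
Title: Protein-Metabolite Covariation Architecture Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds protein-metabolite covariation architectures from
    cohort-scale proteomic and metabolomic abundance matrices. Computes all
    pairwise Pearson correlations with Benjamini-Hochberg control, maps
    measured metabolites through an ontology ancestor closure onto
    reaction, pathway and transporter knowledge to quantify recapitulation
    of established biochemistry, nominates protein predictors of metabolite
    abundance by relaxed LASSO with post-selection FDR, flags extreme
    outlier coefficients, scores metabolites for validation priority,
    annotates nominated edges through physical interactors, and evaluates
    discovery performance by hop-distance enrichment, accessory-member
    Fisher tests and ROC/precision-recall analysis. Includes a synthetic
    multi-omic cohort generator with planted enzyme, transporter and
    adaptor-chain relationships so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    glmnet,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
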