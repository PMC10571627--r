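Package: survenrich
Title: Survival-Based Gene Set Enrichment Analysis for RNA-seq Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Ranks genes by per-gene Cox proportional-hazards log hazard
    ratios fitted on voom-style log-CPM normalized expression and runs
    preranked weighted Kolmogorov-Smirnov gene set enrichment with a
    gene-set permutation null, sign-stratified normalized enrichment
    scores, permutation p-values and Benjamini-Hochberg adjustment, to
    identify biological pathways associated with mortality or survival.
    Also provides the standard fold-change mode (a simplified two-group
    negative-binomial generalized linear model with median-of-ratios size
    factors), a comparison of significant pathway sets between the two
    modes, a synthetic data generator with planted pathway effects, and a
    command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    survival,
    fgsea,
    optparse
Config/testthat/edition: 3
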