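Package: caretile
Title: Tiling CRISPRa Screen Analysis and Targeted Single-Cell Perturbation Mapping
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Calls CRISPRa-responsive elements (CaREs) from dense tiling
    CRISPR activation screens by scoring guides against a non-targeting
    control null and testing 100 bp bins with a sliding-window linear mixed
    model likelihood-ratio test, merging significant bins into elements.
    Identifies element-to-gene regulatory links from targeted single-cell
    perturbation experiments using a covariate-adjusted hurdle test against
    a distal-guide background. Models elements from chromatin features with
    cross-validated logistic regression and a random forest, and integrates
    candidate pairs with Capture-C, Hi-C, enhancer-catalog and
    activity-by-contact evidence. A synthetic-data generator with planted
    ground truth makes every stage testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    Matrix,
    data.table,
    jsonlite,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    lme4,
    optparse
Config/testthat/edition: 3
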