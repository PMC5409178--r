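Package: ddcquant
Title: Quantitative Tests of Neutral Subfunctionalization After Gene Duplication
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to decide whether the subfunctionalization of a duplicated
    gene is adaptive or neutral, built around four quantitative components:
    maximum-likelihood estimation of selection coefficients from competitive
    flow-cytometry count data under a binomial logistic-growth model, with
    censoring rules and assay-resolution summaries; construction and analysis
    of duplication-degeneration-complementation (DDC) fitness landscapes over
    reconstructed evolutionary intermediates, including fitness-class
    clustering and enumeration of neutral mutational paths; a two-state
    phylogenetic hidden Markov model that detects conserved protein regions
    and likelihood-ratio tests for post-duplication relaxation of constraint;
    and exact small-count statistics (Fisher tests, bootstrap confidence
    intervals) for colony-sectoring and localization assays. A synthetic-data
    module generates every input with the statistical structure the assays
    assume, so the full pipeline can be exercised and calibrated without raw
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    ape,
    igraph,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    phangorn
biocViews: Phylogenetics, HiddenMarkovModel, Genetics, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
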