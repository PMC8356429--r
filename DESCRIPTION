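Package: patternxfer
Title: Cross-Species Transfer Learning of Non-Negative Expression Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns non-negative latent expression patterns from single-cell
    RNA-seq with a subset/consensus penalized NMF, identifies pattern-marker
    genes and permutation gene-set enrichment, projects independent datasets
    (single-cell, bulk, or reduced protein panels) into the learned pattern
    space via homolog matching, and associates projected pattern weights with
    treatment groups, binary response (ROC/AUC), and overall survival
    (age-adjusted Cox proportional hazards). Includes a synthetic-data
    generator with planted ground truth for end-to-end validation, a
    kNN-geodesic pseudotime stage, tidy() and glance() methods, and ggplot2
    visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils
Suggests:
    clue,
    fgsea,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
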