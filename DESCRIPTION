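Package: ontorules
Title: Ontology-Guided Conjunctive Rule Learning for Binary Omics Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Induces conjunctive IF-THEN rules over ontology terms that
    discriminate the positive from the negative cells of a two-dimensional
    binary omics matrix (genes by samples). Annotations are propagated along
    the "more general than" partial order of one or more OBO ontologies, and
    rules are searched with a CN2-style beam search inside a
    separate-and-conquer covering loop. An ontology-aware refinement operator
    applies two sound reductions, Redundant Generalization and Redundant
    Non-potential, which prune the rule space without changing the quality of
    the best rule found. Rule quality can be measured by accuracy, F1 or a
    single-point AUC, each paired with an admissible upper bound used for
    pruning, and rule significance is assessed with a likelihood-ratio
    statistic against a chi-square reference. Includes generators for random
    ontologies and planted-rule datasets so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    generics,
    ggplot2,
    igraph,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
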