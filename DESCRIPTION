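Package: cidrex
Title: Chemical-Induced Disease Relation Extraction from Annotated Abstracts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Document-level extraction of chemical-induced disease (CID)
    relations from annotated biomedical abstracts. Implements a convolutional
    neural network over contextual features and dependency paths for
    chemical-disease mention pairs co-occurring in one sentence, a maximum
    entropy (L2 logistic) classifier with sparse linguistic features for pairs
    spanning sentences, MeSH tree-number hypernym filtering at training and
    prediction time, merging of mention-level decisions into document-level
    concept pairs, heuristic post-processing for documents with no extracted
    relation, and micro-averaged precision/recall/F evaluation. Includes
    readers and writers for the PubTator corpus format, a tabular dependency
    parse dialect, MeSH tree-number tables and word-vector files, plus a
    seeded synthetic-corpus generator with planted, learnable relation signal
    so the whole pipeline is trainable and testable end to end without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
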