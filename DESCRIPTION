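Package: biodivrelex
Title: Unsupervised Relation Extraction for Biodiversity Literature
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Labels binary has_time (reproductive condition to temporal
    expression) and has_location (habitat to geographic location) relations
    in entity-annotated biodiversity sentences without any task-specific
    training. Combines high-precision token-type regular-expression rules,
    a dependency-distance matcher, compound-entity grouping, and zero-shot
    boolean question answering / natural language inference templating
    behind a pluggable inference backend. Ships CoNLL-U (with a biodiv
    FEATS extension) and JSONL readers and writers, a seeded synthetic
    corpus generator with gold labels, and the full evaluation suite
    (precision, recall, F1, Matthews correlation, annotator agreement).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
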