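Package: medkgqa
Title: Medical Knowledge-Graph Construction and Memory-Network Question Answering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for mining a coarse-grained medical knowledge
    graph from clinical-style free text and answering single-fact questions over
    it. Implements bootstrapping annotation of entities and relations from seed
    lists with support/confidence/reliability pattern scoring and pluggable
    candidate validation; character-level entity recognition with a bidirectional
    LSTM-CRF whose cell carries an additive, gated context-bridge term fed by
    mined surface patterns; relation classification with a sliding-window
    convolutional network concatenated with a paragraph-context vector; knowledge
    fusion by embedding-based entity alignment and supportability-based
    consistency analysis with two-threshold triage; and a memory-network question
    answering model with region-affinity attention over tuple patches, a trained
    generalization (memory-utility) module, and margin-ranking training. Ships a
    synthetic clinical-corpus generator with a ground-truth ledger so every stage
    is testable without access to real health records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
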