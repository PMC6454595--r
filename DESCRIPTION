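Package: medner
Title: Hybrid Named Entity Recognition for Chinese Electronic Medical Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Recognizes clinical named entities (anatomy, surgery, drug,
    independent symptom, symptom description) in Chinese electronic medical
    record narratives. Implements a character-level BiLSTM-CRF sequence tagger
    and an attention-augmented variant that injects document-level context to
    reduce tagging inconsistency, together with three auxiliary correction
    passes: entity boundary auto-correction against an entity base built from
    training annotations, drug-dictionary longest-match rectification and
    extraction, and rule-based boundary post-processing. Includes strict
    entity-level precision/recall/F1 evaluation, a document-level tag
    consistency metric, readers and writers for tagged-item and CoNLL-style
    BIO formats, and a seeded synthetic corpus generator so the full pipeline
    is trainable and testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
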