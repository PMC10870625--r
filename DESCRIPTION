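Package: deidfr
Title: Distant-Supervision De-Identification of French Clinical Text
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building de-identification corpora from French
    clinical free text without manual labels. Parses HTML documents to
    visible text while tracking the source position of every character,
    detects eight categories of personally identifiable information
    (patient and practitioner names, dates, phone numbers, emails,
    streets, postal codes, cities) with rules, gazetteers and per-record
    metadata, encodes the result as BIO token labels with patient-level
    train/validation/test splits, and masks the original documents
    through the offset map. Includes entity-level precision/recall/F1
    scoring, Fleiss kappa inter-annotator agreement with bootstrap
    intervals, readers and writers for Prodigy-style JSONL and CoNLL
    files, and a seeded generator of synthetic clinical documents with
    gold annotations and companion gazetteer files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stringi,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
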