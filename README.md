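# deidfr

Distant-supervision de-identification of French clinical free text.

Hospital documents (discharge summaries, consultation reports, letters)
are full of personally identifiable information — patient and
practitioner names, dates, phone numbers, emails, street addresses,
postal codes, city names — that must be removed before the records can
be reused for research. Training a named-entity recognizer to find that
PII normally requires expensive manual annotation. `deidfr` implements
the alternative: *distant supervision*, where noisy training labels are
produced automatically by matching the text against national knowledge
bases (address and health-professional directories), regular-expression
patterns, contextual triggers, and each record's own metadata (the
patient's name and birthdate are already in the database — if they
appear in the text, they are PII by construction).

The package covers the whole corpus-building and evaluation apparatus
around that idea, for eight PII categories
(`PATIENT`, `DOCTOR`, `DATE`, `EMAIL`, `PHONE`, `STR`, `ZIP`, `VILLE`):

* **Ingest** — a tolerant HTML-to-text extractor that records, for every
  extracted character, the span of raw characters it was decoded from,
  so stand-off annotations can always be projected back onto the
  original markup; deterministic French sentence splitting and
  tokenization (offsets are 0-based, half-open everywhere).
* **Gazetteers** — loaders for files in the Base Adresse Nationale
  column schema (`nom_voie`, `code_postal`, `nom_commune`) and the
  Health Directory schema (`Nom d'exercice`, `Prenom d'exercice`), with
  normalization (case/diacritic-insensitive), compound-name expansion
  (`JEAN-PIERRE` → `JEAN-PIERRE`, `JEAN`, `PIERRE`) and ambiguity
  filtering (`DE`, `DU`, `LE`, ... are never dictionary entries).
* **Rule annotator** — per-category detectors (date patterns with bound
  checks, phone-group patterns, postal codes with contextual support,
  an email grammar, street-cue anchored spans, longest-match city
  lookup, practitioner role triggers `Dr`/`Docteur`/`Pr`, patient
  metadata echoes) pooled by a cascade that resolves overlaps
  longest-span-first with a fixed category priority.
* **BIO corpus** — encoding/decoding between mentions and
  `B-`/`I-`/`O` token tags (with repair of invalid sequences),
  entity-sentence filtering, a hash-based patient-level 80/10/10 split
  (all documents of a patient land in the same partition), corpus
  statistics, and Prodigy-style JSONL plus CoNLL readers/writers.
* **Evaluation** — entity-level precision/recall/F1 with strict
  (exact span + type) and token-level matching, per-class and
  micro/macro/weighted aggregates.
* **Agreement** — Fleiss kappa over token labels, per-tag one-vs-rest
  kappas, pairwise rater agreement, document-level bootstrap confidence
  intervals.
* **Masking** — placeholder or surrogate replacement of PII in the
  *original HTML* through the offset map, preserving all markup.
* **Synthetic corpus** — a seeded generator of French-style clinical
  HTML documents with gold annotations and matching gazetteer files, so
  everything above is testable without access to any real data.

The metrics are the standard NER definitions: `P = TP/(TP+FP)`,
`R = TP/(TP+FN)`, `F1 = 2PR/(P+R)`; Fleiss kappa is
`(P̄ − P̄e)/(1 − P̄e)` with `P̄` the mean observed pairwise agreement per
item and `P̄e` the chance agreement from the category marginals.

Neural sequence taggers are out of scope by design: the evaluation
functions accept predictions from any external tagger in the same JSONL
dialect, which is the full extent of the model seam.

## Worked example

```r
library(deidfr)

# A tiny document with letterhead-style PII
doc <- source_document(
  doc_id = "doc1", patient_id = "pat1",
  raw = paste0("<p>CHU DE RENNES</p>",
               "<p>Dr JEAN DUPONT - 12 RUE DE LA PAIX, 35000 RENNES</p>",
               "<p>Monsieur Paul MARTIN, ne le 02/07/1985, va bien.</p>"),
  metadata = list(patient_first_name = "Paul", patient_last_name = "MARTIN",
                  birthdate = as.Date("1985-07-02"))
)

gaz <- list(VILLE = gazetteer("VILLE", "Rennes"),
            ZIP   = gazetteer("ZIP", "35000"))
parsed <- parse_document(doc)
keys <- patient_record_keys(doc)
ann <- lapply(parsed$sentences, annotate_sentence,
              gazetteers = gaz, keys = keys)
ann[[2]]
#>   category token_first token_last char_start char_end    source        rule_id
#> 1   DOCTOR           1          2          3       14   context doctor-trigger
#> 2      STR           4          8         17       34   pattern     street-cue
#> 3      ZIP          10         10         36       41 gazetteer            zip
#> 4    VILLE          11         11         42       48 gazetteer           city

bio_encode(parsed$sentences[[3]], ann[[3]])
#> [1] "O"  "B-PATIENT"  "I-PATIENT"  "O"  "O"  "O"  "B-DATE"  "O"  "O"  "O"  "O"

spans <- doc_level_spans(parsed$sentences, ann)
cat(mask_document(doc, spans, parsed$map))
#> <p>CHU DE [VILLE]</p><p>Dr [DOCTOR] - [STR], [ZIP] [VILLE]</p>
#> <p>Monsieur [PATIENT], ne le [DATE], va bien.</p>
```

The mention frame is stand-off: each row names a category, the covered
token range, the sentence-local character span, and the rule that
produced it. `mask_document()` rewrites the *raw HTML*, not the
extracted text — every byte outside the masked spans is untouched.

For a corpus-scale run, `gen_corpus()` + `gen_gazetteers()` produce a
synthetic corpus and `run_distant_supervision()` executes the full
pipeline (annotate, keep sentences with at least one entity, split by
patient, write JSONL/CoNLL/stats). A thin command-line front end over
these functions ships at `inst/cli/deid.R`.

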