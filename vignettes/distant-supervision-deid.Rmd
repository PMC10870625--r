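---
title: "Distant-supervision de-identification: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distant-supervision de-identification: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deidfr)
```

## The problem and the approach

Clinical documents cannot be shared for research while they contain
personally identifiable information (PII). Named-entity recognizers can
find PII, but training them classically requires manually annotated
clinical text — expensive, slow, and itself a privacy exposure. The
approach implemented here removes the manual-annotation bottleneck:
labels are generated automatically ("distant supervision") from three
sources of evidence that are available without any annotator:

1. **Knowledge bases.** National directories provide exhaustive lists of
   street names, postal codes, municipalities and healthcare
   professionals. A normalized dictionary match against these lists is a
   (noisy) PII label.
2. **Patterns and context.** Dates, phone numbers, postal codes and
   emails have rigid lexical shapes; street names follow cue words
   (`RUE`, `AVENUE`, ...); practitioner names follow titles (`Dr`,
   `Docteur`, `Pr`). Orthography (capitalization) separates names from
   ordinary words.
3. **Record metadata.** The patient's own first name, last name and
   birthdate are stored with the record; any occurrence of them in the
   text is PII by construction.

The output is a BIO-tagged corpus intended for training any downstream
sequence tagger. The tagger itself is deliberately outside this package;
the evaluation module accepts any tagger's output in the same JSONL
dialect.

## Offset discipline

Everything downstream depends on one invariant: annotations made on
extracted, sentence-split text must be projectable back onto the raw
HTML, because the deliverable of de-identification is a *masked
original document*, not a masked plain-text shadow.

All offsets are 0-based and half-open. The HTML extractor returns, for
every extracted character, the span `[src_start, src_end)` of raw
characters it came from. Three cases are worth naming:

* a plain character maps to a width-1 span;
* a decoded entity reference (`&amp;` → `&`) maps to the full
  `&...;` span, so masking a span containing it removes the whole
  reference;
* newlines synthesized at block-element boundaries map to a zero-width
  position (they do not exist in the source and are skipped when
  masking).

A mention whose extracted span crosses markup (e.g.
`<b>JEAN</b> DUPONT`) decomposes into maximal runs of contiguous source
characters; each run is replaced separately and the markup survives.
This is also why masking is done span-wise on the raw string rather than
by re-serializing a parse tree: byte-for-byte conservation outside the
masked ranges is testable and tested.

Global token offsets (`start_char`, `end_char`) are defined as indices
into the *decoded character stream* of the raw document. Input files
occasionally print global offsets inconsistent with their own token
lengths; we treat the sentence-local `start`/`end` fields as
authoritative and recompute global offsets from the map.

## Sentence splitting and tokenization

No standard defines "the" French clinical tokenizer, so the rules are
fixed and deterministic to make the corpus reproducible:

* Sentences end at `.`, `!`, `?`, `…` followed by whitespace and an
  uppercase letter or digit — unless the preceding word is a known
  abbreviation (`Dr`, `Pr`, `M`, `Mme`, month abbreviations, ...) or a
  single initial. Every newline is a hard boundary: extracted HTML puts
  each block element on its own line, which keeps letterhead fields
  (hospital, address, phone) as separate one-line sentences.
* Tokens are non-whitespace runs, split at punctuation *except*
  word-internal hyphens and apostrophes (`JEAN-PIERRE`, `l'examen`),
  `@`/`.` inside emails, and `.`/`/`/`-` separators inside numeric runs
  (`12/03/2020`, `02.99.28.43.21` are single tokens). Tokenizing a
  token's own text returns that token (idempotence), which the tests
  exercise.

## The detector cascade

Each detector emits candidate stand-off mentions; the cascade pools them
and resolves overlaps. Parameters that matter:

* `context_window = 4` tokens: the distance within which a role trigger
  finds its name, and a postal code finds its supporting city or street
  cue. Window 4 accommodates interposed tokens ("Monsieur le Docteur
  JEAN DUPONT", "Dr . DUPONT").
* Phone groups: 3 to 6 two-digit groups, or one contiguous 10-digit run
  starting with 0. French numbers have five pairs; the floor of 3
  admits short switchboard forms (`00.00.00`), the ceiling of 6 covers
  the longest printed grouping seen in practice.
* Date bounds: numeric forms validate day ≤ 31 and month ≤ 12, which
  keeps arbitrary `45/99/2020`-like fractions out. Two-digit years are
  accepted (`dd/mm/yy`).
* Lowercase dictionary hits (cities, streets) require contextual
  support — an adjacent postal code or street cue — because French city
  names collide heavily with ordinary words and surnames. Capitalized
  hits stand alone. This is the main precision/recall dial of the
  lookup detectors.
* Overlap resolution: longest span first; ties broken by the fixed
  priority `PATIENT > DOCTOR > EMAIL > PHONE > DATE > STR > ZIP >
  VILLE`, then position. The priority puts metadata-grounded and
  structurally unambiguous classes ahead of lookup classes: when the
  patient's name is also a plausible practitioner name, the metadata
  match wins; when a date could be read as phone pairs, the more
  specific pattern has already produced the longer span. The result is
  always non-overlapping and sorted.
* Practitioner titles are *triggers*, not parts of the span: "Docteur
  JEAN DUPONT" yields a mention over `JEAN DUPONT` only. Abbreviation
  entries are split accordingly: `Ave`→`Avenue`, `St`→`Saint` are
  textual expansions (street cues), while `Dr`/`Pr` are role markers.
* Masking placeholders (`[DOCTOR]` etc.) are recognized and excluded
  from name candidates, making placeholder masking idempotent:
  re-running the cascade on a masked document finds nothing.

The dictionary stop set (`DE`, `DU`, `DES`, `LE`, `LA`, `L`, `D`, plus
all single letters, minimum entry length 2) removes entries that are
overwhelmingly more often articles than names; it is a configuration
field because directory dumps differ in how much such noise they carry.

## Corpus construction

Only sentences with at least one mention are kept for the corpus (a
de-identification tagger learns nothing from all-`O` sentences at this
scale, and the filter shrinks the corpus by an order of magnitude).

The train/validation/test split is by patient, not by document: all
documents of a patient share a partition, otherwise near-duplicate
letters for one patient would leak across splits. Assignment hashes the
patient identifier salted with the seed (FNV-1a with a MurmurHash3
finalizer, mapped to `[0, 1)` and cut at 0.8/0.9). A hash rather than a
shuffle means the assignment is reproducible with no stored state and a
patient's partition never changes when the corpus grows. Over 10,000
patients the realized train fraction is binomially concentrated within
about ±0.012 of 0.8 (three standard errors); the acceptance suite
checks ±0.02.

Percentage shares in corpus statistics use half-up rounding at one
decimal, fixed explicitly because published tables rarely state their
rounding convention and banker's rounding (the R default) differs at
the 0.05 boundary.

## Evaluation and agreement

The default matching criterion is **strict**: a prediction counts only
if category, start and end all equal a gold mention, one-to-one. The
token-level criterion is provided alongside (partial overlap earns
partial credit); published per-class supports are consistent with
mention counts, so strict is the default. Micro aggregates pool counts;
macro averages per-class metrics unweighted; weighted averages by
support. Zero denominators define the metric as 0 with a `degenerate`
flag rather than `NaN`.

Bundled under `inst/extdata/` are the per-class score tables of a
published large-scale French clinical de-identification evaluation (a
neural tagger and a rule-based system) and that study's corpus count
table. They are used as *arithmetic fixtures*: the metric engine must
reproduce their internal identities — each F1 is the harmonic mean of
its P and R within printed rounding, the weighted F1 is the
support-weighted mean of the per-class F1s, per-class supports pool to
the micro support, and the corpus shares round to the printed
percentages. The study's headline end-to-end scores were computed on
private hospital data and are not reproducible here; the identities
are.

Inter-annotator agreement is Fleiss kappa over token labels, with `O`
as a first-class category (tokens outside entities are still rated).
Per-tag agreement is the binary one-vs-rest reduction. Pairwise
agreement is Fleiss restricted to the two raters (equivalently Scott's
pi) over their shared documents, `NA` when a pair shares nothing.
Confidence intervals are percentile bootstrap over *documents* (the
exchangeable unit of an annotation campaign — tokens within a document
are strongly dependent), 1,000 replicates by default, deterministic
given the seed. When every rating falls in one category the chance
agreement is 1 and kappa is defined as 1 with a degeneracy flag.

## The synthetic corpus

Real clinical corpora and the national directories cannot be
redistributed, so the package ships a generator that emulates the
*structural* properties the pipeline depends on: HTML documents made of
one-sentence paragraphs — a header, letterhead-style lines (practitioner
with title, address `number STREET, ZIP CITY` components, phone,
email), patient-name and birthdate echoes, dated body lines, neutral
clinical filler — with gold mentions recorded at generation time.
Categories are drawn from a frequency profile defaulting to the
per-class distribution of a large automatically annotated clinical
training corpus (DATE 27.2%, DOCTOR 21.4%, VILLE 14.0%, PHONE 12.2%,
PATIENT 10.2%, ZIP 7.2%, STR 6.4%, EMAIL 1.5%), so synthetic corpora
stress the classes realistically.

The noise model applies per-word independent corruption *before gold
offsets are recorded*: typos (adjacent swap or deletion), accent
removal, and cue-word abbreviation substitution. Gold spans therefore
address the corrupted surface — exactly the situation distant
supervision faces, where the "gold" label is itself derived from noisy
text. `gazetteer_coverage` controls the fraction of the generated name
pools present in the emitted gazetteer files, decoupling "the name
exists" from "the dictionary knows it".

What the generator does **not** emulate: real clinical narrative,
spelling variation beyond the three noise operators, table/figure
layout, OCR artifacts, ambiguous person/place homonyms, and nested or
discontinuous entities. Passing the synthetic integration tests
therefore shows the machinery is correct (offsets, detection logic,
resolution, splitting, masking), not that the rule set would reach any
particular score on real hospital text — on real data the published
rule-based reference numbers (e.g. PATIENT precision near 0.55) show
how much harder the open world is.

Name, street and city vocabularies are small bundled lists, not
extracts of any real directory.

## Problem sizes and numerical choices

The test suite generates its corpora at module scale (typically 3–100
patients, ~13 sentences per document); the acceptance checks use 200
documents for the masking round-trip, 120 documents for the cascade
integration test, 1,000 random mention sets for the BIO round-trip, 100
random rating matrices for the kappa oracle and 10,000 patients for the
split contract — sizes chosen so the whole suite runs in a few minutes
on one core while keeping every binomial bound meaningful.

Degenerate inputs are defined, not rejected: empty documents parse to
empty maps, whitespace-only text splits to zero sentences, empty
corpora produce empty files, all-`O` taggings decode to zero mentions,
and invalid BIO sequences are repaired (`I-X` after `O` opens a new
mention) on the view that a corpus reader should never crash on a
tagger's output.

## Known limitations

* Sentence splitting and tokenization are rule-based; exotic layouts
  (tables linearized in document order, lists) may split oddly.
* The DOCTOR/PATIENT distinction relies on metadata and titles; an
  untitled practitioner absent from the directory is invisible, and a
  patient sharing a name with a practitioner is resolved by priority,
  not by context understanding.
* No coreference, no nested entities, French only.
* Surrogate masking draws from the synthetic vocabulary; it guarantees
  the replacement differs from the original but not cross-document
  consistency (deliberately — linkable surrogates are a re-identification
  channel unless managed).
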