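#' The eight PII categories
#'
#' Returns the fixed, ordered vector of personally-identifiable-information
#' categories handled by the package: patient names, practitioner names,
#' dates, emails, phone numbers, street addresses, postal codes and city
#' names. The ordering is stable and is used for report columns and for
#' tie-breaking nowhere (tie-breaking uses the priority in
#' [rule_config()]).
#'
#' @return Character vector of length eight.
#' @export
#' @examples
#' pii_categories()
pii_categories <- function() {
  c("PATIENT", "DOCTOR", "DATE", "EMAIL", "PHONE", "STR", "ZIP", "VILLE")
}

assert_category <- function(x) {
  bad <- setdiff(unique(x), pii_categories())
  if (length(bad)) {
    stop("unknown PII category: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(x)
}

#' Construct a source document
#'
#' A source document couples the raw (usually HTML) text of one clinical
#' document with the record metadata that drives metadata-based detection:
#' the patient's name and birthdate, and optional contact details.
#'
#' @param doc_id Opaque document identifier, unique within a corpus.
#' @param patient_id Opaque, non-empty patient identifier. All documents of
#'   one patient are routed to the same split partition.
#' @param raw Full source text (HTML or plain text).
#' @param metadata Named list; recognised fields are
#'   `patient_first_name`, `patient_last_name`, `birthdate` (a `Date` or
#'   `"YYYY-MM-DD"` string) and optional `address`, `phone`, `email`.
#' @param dialect One of `"native-HTML"`, `"CDA-R2"`, `"XML"`,
#'   `"PDF-derived-HTML"`, `"plain"`. Carried as provenance only.
#'
#' @return An object of class `source_document`.
#' @export
source_document <- function(doc_id, patient_id, raw, metadata = list(),
                            dialect = "native-HTML") {
  stopifnot(is.character(doc_id), length(doc_id) == 1L, nzchar(doc_id))
  if (!is.character(patient_id) || length(patient_id) != 1L || !nzchar(patient_id)) {
    stop("patient_id must be a non-empty string", call. = FALSE)
  }
  dialect <- match.arg(dialect,
                       c("native-HTML", "CDA-R2", "XML", "PDF-derived-HTML", "plain"))
  structure(
    list(doc_id = doc_id, patient_id = patient_id, raw = raw,
         metadata = metadata, dialect = dialect),
    class = "source_document"
  )
}

#' @export
print.source_document <- function(x, ...) {
  cat("<source_document> ", x$doc_id,
      " (patient ", x$patient_id, ", ", x$dialect, ", ",
      nchar(x$raw), " chars)\n", sep = "")
  invisible(x)
}

empty_tokens <- function() {
  data.frame(text = character(), start = integer(), end = integer(),
             start_char = integer(), end_char = integer(), id = integer(),
             stringsAsFactors = FALSE)
}

#' Construct a sentence
#'
#' A sentence is a stretch of extracted text together with its tokens. All
#' offsets are 0-based and half-open: a token with `start = 0`, `end = 6`
#' covers the first six characters of the sentence text. Each token
#' additionally carries `start_char`/`end_char`, its position in the source
#' document's decoded character stream, so that annotations made on the
#' sentence can be projected back onto the original document.
#'
#' @param text Sentence text.
#' @param tokens Data frame with columns `text`, `start`, `end`,
#'   `start_char`, `end_char`, `id` (0-based token index).
#' @param doc_ref Identifier of the document the sentence came from.
#' @param sent_index 0-based sentence index within the document.
#' @param text_offset 0-based offset of the sentence within the extracted
#'   document text.
#'
#' @return An object of class `sentence`.
#' @export
sentence <- function(text, tokens = NULL, doc_ref = NA_character_,
                     sent_index = 0L, text_offset = 0L) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.null(tokens)) tokens <- tokenize(text)
  validate_tokens(text, tokens)
  structure(
    list(text = text, tokens = tokens, doc_ref = doc_ref,
         sent_index = as.integer(sent_index),
         text_offset = as.integer(text_offset)),
    class = "sentence"
  )
}

validate_tokens <- function(text, tokens) {
  req <- c("text", "start", "end", "start_char", "end_char", "id")
  if (!all(req %in% names(tokens))) {
    stop("tokens must have columns: ", paste(req, collapse = ", "), call. = FALSE)
  }
  if (nrow(tokens) == 0L) return(invisible(tokens))
  if (any(tokens$start >= tokens$end)) stop("token with start >= end", call. = FALSE)
  if (any(tokens$end - tokens$start != nchar(tokens$text))) {
    stop("token span length does not match token text", call. = FALSE)
  }
  n <- nchar(text)
  if (any(tokens$end > n) || any(tokens$start < 0L)) {
    stop("token span outside sentence text", call. = FALSE)
  }
  if (is.unsorted(tokens$start, strictly = TRUE) && nrow(tokens) > 1L) {
    stop("tokens must be ascending in start", call. = FALSE)
  }
  if (nrow(tokens) > 1L && any(tokens$start[-1L] < tokens$end[-nrow(tokens)])) {
    stop("tokens overlap", call. = FALSE)
  }
  got <- substring(text, tokens$start + 1L, tokens$end)
  if (!all(got == tokens$text)) {
    stop("token text does not match sentence substring", call. = FALSE)
  }
  invisible(tokens)
}

#' @export
print.sentence <- function(x, ...) {
  cat("<sentence> ", encodeString(x$text, quote = '"'),
      " (", nrow(x$tokens), " tokens)\n", sep = "")
  invisible(x)
}

#' Construct a set of entity mentions
#'
#' Mentions are stand-off annotations: they never mutate the text, so the
#' same mention set can drive BIO export, evaluation and masking. A mention
#' covers an inclusive token range `[token_first, token_last]` and the
#' corresponding sentence-local character span `[char_start, char_end)`.
#'
#' @param category PII category, see [pii_categories()].
#' @param token_first,token_last Inclusive 0-based token indices.
#' @param char_start,char_end Sentence-local 0-based half-open char span.
#' @param source Provenance: `"pattern"`, `"gazetteer"`, `"metadata"`,
#'   `"context"` or `"manual"`.
#' @param rule_id Free-form identifier of the producing rule.
#'
#' @return Data frame with one row per mention.
#' @export
entity_mentions <- function(category = character(), token_first = integer(),
                            token_last = integer(), char_start = integer(),
                            char_end = integer(), source = character(),
                            rule_id = character()) {
  assert_category(category)
  n <- length(category)
  if (length(source) %in% c(0L, 1L)) source <- rep(if (length(source)) source else "manual", n)
  if (length(rule_id) %in% c(0L, 1L)) rule_id <- rep(if (length(rule_id)) rule_id else "", n)
  out <- data.frame(
    category = as.character(category),
    token_first = as.integer(token_first),
    token_last = as.integer(token_last),
    char_start = as.integer(char_start),
    char_end = as.integer(char_end),
    source = as.character(source),
    rule_id = as.character(rule_id),
    stringsAsFactors = FALSE
  )
  if (nrow(out) && any(out$token_first > out$token_last)) {
    stop("mention with token_first > token_last", call. = FALSE)
  }
  out
}

# Build mentions from token index ranges, deriving char spans from tokens.
mentions_from_tokens <- function(sent_tokens, category, token_first, token_last,
                                 source, rule_id) {
  n <- length(token_first)
  if (n == 0L) return(entity_mentions())
  entity_mentions(
    category = rep_len(category, n),
    token_first = token_first,
    token_last = token_last,
    char_start = sent_tokens$start[token_first + 1L],
    char_end = sent_tokens$end[token_last + 1L],
    source = rep_len(source, n),
    rule_id = rep_len(rule_id, n)
  )
}

#' Surface string of a mention
#'
#' @param sent A [sentence()].
#' @param mention One-row mention data frame (or a row index into a larger
#'   mention frame via `mention[i, ]`).
#' @return The sentence substring covered by the mention.
#' @export
#' @examples
#' s <- sentence("CENTRE HOSPITALIER UNIVERSITAIRE DE RENNES")
#' m <- entity_mentions("VILLE", 4L, 4L, 36L, 42L, "gazetteer", "city")
#' span_surface(s, m)
span_surface <- function(sent, mention) {
  stopifnot(inherits(sent, "sentence"), nrow(mention) == 1L)
  cs <- mention$char_start
  ce <- mention$char_end
  if (is.na(cs) || is.na(ce) || cs < 0L || ce > nchar(sent$text) || cs >= ce) {
    stop("malformed mention: char span [", cs, ",", ce,
         ") invalid for sentence of length ", nchar(sent$text), call. = FALSE)
  }
  substring(sent$text, cs + 1L, ce)
}
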