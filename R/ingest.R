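# HTML ingestion with reversible character-offset tracking.
#
# The parser never normalises the source: every extracted character records
# the half-open span [src_start, src_end) of raw-document characters it was
# decoded from, so annotations made on the extracted text can be projected
# back onto the original HTML for masking. Offsets index decoded characters
# of the raw string, 0-based.

BLOCK_ELEMENTS <- c(
  "p", "div", "br", "li", "ul", "ol", "dl", "dt", "dd", "table", "tbody",
  "thead", "tfoot", "tr", "td", "th", "caption", "h1", "h2", "h3", "h4",
  "h5", "h6", "blockquote", "pre", "hr", "form", "fieldset", "address",
  "article", "aside", "footer", "header", "main", "nav", "section", "body",
  "html", "head", "title"
)

HTML_ENTITIES <- c(
  amp = "&", lt = "<", gt = ">", quot = "\"", apos = "'", nbsp = " ",
  eacute = "é", egrave = "è", ecirc = "ê", euml = "ë",
  agrave = "à", acirc = "â", auml = "ä",
  icirc = "î", iuml = "ï", ocirc = "ô", ouml = "ö",
  ugrave = "ù", ucirc = "û", uuml = "ü",
  ccedil = "ç", oelig = "œ",
  Eacute = "É", Egrave = "È", Ecirc = "Ê", Agrave = "À",
  Ccedil = "Ç", Ocirc = "Ô",
  deg = "°", middot = "·", hellip = "…", laquo = "«",
  raquo = "»", ndash = "–", mdash = "—", rsquo = "’",
  copy = "©", times = "×"
)

new_offset_map <- function(src_start = integer(), src_end = integer()) {
  structure(list(src_start = as.integer(src_start),
                 src_end = as.integer(src_end)),
            class = "offset_map")
}

#' @export
print.offset_map <- function(x, ...) {
  cat("<offset_map> ", length(x$src_start), " extracted characters\n", sep = "")
  invisible(x)
}

# Decode one character-data segment of HTML (no tags inside). Returns the
# decoded characters and, per character, the raw span it came from.
# seg_offset is the 0-based position of the segment in the raw document.
decode_charrefs <- function(segment, seg_offset) {
  n <- nchar(segment)
  if (n == 0L) {
    return(list(chars = character(), src_start = integer(), src_end = integer()))
  }
  refs <- stringi::stri_locate_all_regex(
    segment, "&(?:[A-Za-z][A-Za-z0-9]{1,30}|#[0-9]{1,7}|#x[0-9A-Fa-f]{1,6});"
  )[[1]]
  chars <- strsplit(segment, "", fixed = TRUE)[[1]]
  src_start <- seg_offset + seq_len(n) - 1L
  src_end <- src_start + 1L
  if (!is.na(refs[1L, 1L])) {
    keep <- rep(TRUE, n)
    for (k in seq_len(nrow(refs))) {
      a <- refs[k, 1L]; b <- refs[k, 2L]
      body <- substr(segment, a + 1L, b - 1L)
      decoded <- if (startsWith(body, "#x") || startsWith(body, "#X")) {
        intToUtf8(strtoi(substring(body, 3L), 16L))
      } else if (startsWith(body, "#")) {
        intToUtf8(strtoi(substring(body, 2L), 10L))
      } else if (body %in% names(HTML_ENTITIES)) {
        HTML_ENTITIES[[body]]
      } else {
        NA_character_  # unknown named reference: keep literal text
      }
      if (is.na(decoded)) next
      chars[a] <- decoded
      src_end[a] <- seg_offset + b
      keep[(a + 1L):b] <- FALSE
    }
    chars <- chars[keep]
    src_start <- src_start[keep]
    src_end <- src_end[keep]
  }
  list(chars = chars, src_start = src_start, src_end = src_end)
}

#' Extract visible text from HTML with a source-offset map
#'
#' Tolerant HTML-to-text extraction. Tags, comments and the content of
#' `<script>`/`<style>` elements are dropped; character references are
#' decoded; block-level elements contribute a single newline so that
#' letterhead lines stay separate, inline elements contribute nothing.
#' Every extracted character carries the span of raw characters it was
#' decoded from (a decoded entity reference maps to its full `&...;` span;
#' synthesised newlines map to the zero-width position of the tag that
#' produced them).
#'
#' @param raw HTML source, or plain text when `dialect = "plain"`.
#' @param dialect `"html"` (default, any of the HTML-derived inputs) or
#'   `"plain"` for an identity map.
#' @return A list with `text` (extracted text) and `map` (an `offset_map`
#'   with parallel integer vectors `src_start`, `src_end`, one entry per
#'   extracted character, 0-based half-open into `raw`).
#' @export
#' @examples
#' parse_html("<p>Bonjour</p>")$text
parse_html <- function(raw, dialect = c("html", "plain")) {
  dialect <- match.arg(dialect)
  stopifnot(is.character(raw), length(raw) == 1L)
  if (is.na(raw)) raw <- ""
  if (dialect == "plain" ||
      (!grepl("<", raw, fixed = TRUE) && !grepl("&", raw, fixed = TRUE))) {
    n <- nchar(raw)
    return(list(text = raw,
                map = new_offset_map(seq_len(n) - 1L, seq_len(n))))
  }
  skip <- stringi::stri_locate_all_regex(
    raw,
    paste0("(?is)<!--.*?-->",
           "|<script\\b[^>]*>.*?(?:</script\\s*>|$)",
           "|<style\\b[^>]*>.*?(?:</style\\s*>|$)",
           "|<[^>]*>")
  )[[1]]
  pieces_chars <- list()
  pieces_start <- list()
  pieces_end <- list()
  pos <- 1L  # 1-based cursor in raw
  last_is_nl <- TRUE  # suppress leading newline
  emit_text <- function(from, to) {
    if (to < from) return(invisible())
    seg <- substr(raw, from, to)
    dec <- decode_charrefs(seg, from - 1L)
    if (length(dec$chars)) {
      i <- length(pieces_chars) + 1L
      pieces_chars[[i]] <<- dec$chars
      pieces_start[[i]] <<- dec$src_start
      pieces_end[[i]] <<- dec$src_end
      last_is_nl <<- dec$chars[length(dec$chars)] == "\n"
    }
    invisible()
  }
  if (!is.na(skip[1L, 1L])) {
    for (k in seq_len(nrow(skip))) {
      a <- skip[k, 1L]; b <- skip[k, 2L]
      emit_text(pos, a - 1L)
      tag <- substr(raw, a, b)
      nm <- tolower(stringi::stri_match_first_regex(tag, "^</?\\s*([A-Za-z][A-Za-z0-9]*)")[, 2L])
      if (!is.na(nm) && nm %in% BLOCK_ELEMENTS && !last_is_nl) {
        i <- length(pieces_chars) + 1L
        pieces_chars[[i]] <- "\n"
        pieces_start[[i]] <- a - 1L
        pieces_end[[i]] <- a - 1L  # zero-width: not present in source
        last_is_nl <- TRUE
      }
      pos <- b + 1L
    }
  }
  emit_text(pos, nchar(raw))
  chars <- unlist(pieces_chars, use.names = FALSE)
  if (is.null(chars)) chars <- character()
  src_start <- unlist(pieces_start, use.names = FALSE)
  src_end <- unlist(pieces_end, use.names = FALSE)
  while (length(chars) && chars[length(chars)] == "\n") {
    chars <- chars[-length(chars)]
    src_start <- src_start[-length(src_start)]
    src_end <- src_end[-length(src_end)]
  }
  list(text = paste(chars, collapse = ""),
       map = new_offset_map(src_start, src_end))
}

SENTENCE_ABBREVIATIONS <- c(
  "Dr", "Pr", "Prof", "M", "Mr", "Mme", "Mlle", "St", "Ste", "cf", "etc",
  "janv", "févr", "fevr", "avr", "juil", "sept", "oct", "nov",
  "déc", "dec"
)

#' Split text into sentences
#'
#' Deterministic punctuation/capitalisation splitter: a sentence boundary
#' occurs after sentence-final punctuation (`.`, `!`, `?`, `…`)
#' followed by whitespace when the next character is an uppercase letter or
#' digit, unless the preceding word is a known abbreviation (titles such as
#' "Dr"/"Mme", month abbreviations) or a single uppercase initial. Every
#' newline is additionally a hard boundary, which keeps the one-line-per-
#' field letterhead of clinical HTML as separate sentences.
#'
#' @param text Character scalar.
#' @return Data frame with columns `text` (trimmed sentence) and `offset`
#'   (0-based position of the sentence within `text`). Whitespace-only
#'   input yields zero rows.
#' @export
#' @examples
#' split_sentences("Le patient va bien. Il sort demain.")
split_sentences <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  out_text <- character()
  out_off <- integer()
  if (is.na(text) || !nzchar(trimws(text))) {
    return(data.frame(text = out_text, offset = out_off, stringsAsFactors = FALSE))
  }
  lines <- stringi::stri_locate_all_regex(text, "[^\n]+")[[1]]
  upper_start <- "[A-Z0-9ÀÂÄÉÈÊËÎÏÔÖÙÛÜÇ]"
  for (k in seq_len(nrow(lines))) {
    la <- lines[k, 1L]; lb <- lines[k, 2L]
    line <- substr(text, la, lb)
    if (!nzchar(trimws(line))) next
    cand <- stringi::stri_locate_all_regex(
      line, paste0("[.!?…]+\\s+(?=", upper_start, ")")
    )[[1]]
    cuts <- integer()  # 1-based position in line of last char of each sentence
    if (!is.na(cand[1L, 1L])) {
      for (j in seq_len(nrow(cand))) {
        p <- cand[j, 1L]
        prev <- stringi::stri_match_last_regex(substr(line, 1L, p - 1L),
                                               "([\\p{L}\\p{N}'’-]+)$")[, 2L]
        if (!is.na(prev)) {
          if (prev %in% SENTENCE_ABBREVIATIONS) next
          if (grepl("^\\p{Lu}$", prev, perl = TRUE)) next  # initial like "J."
        }
        # end of the punctuation run
        run <- stringi::stri_locate_first_regex(
          substr(line, p, nchar(line)), "^[.!?…]+")
        cuts <- c(cuts, p + run[1L, 2L] - 1L)
      }
    }
    starts <- c(1L, cuts + 1L)
    ends <- c(cuts, nchar(line))
    for (j in seq_along(starts)) {
      raw_piece <- substr(line, starts[j], ends[j])
      m <- stringi::stri_locate_first_regex(raw_piece, "\\S(?s:.*\\S)?")
      if (is.na(m[1L, 1L])) next
      piece <- substr(raw_piece, m[1L, 1L], m[1L, 2L])
      out_text <- c(out_text, piece)
      out_off <- c(out_off, la - 1L + starts[j] - 1L + m[1L, 1L] - 1L)
    }
  }
  data.frame(text = out_text, offset = out_off, stringsAsFactors = FALSE)
}

TOKEN_PATTERN <- paste0(
  # email addresses kept whole
  "[\\p{L}\\p{N}][\\p{L}\\p{N}._%+-]*@[\\p{L}\\p{N}-]+(?:\\.[\\p{L}\\p{N}-]+)+",
  # numeric runs with internal . / - separators (dates, dotted phones)
  "|\\p{N}+(?:[./–-]\\p{N}+)+",
  # words and alphanumerics with internal hyphens/apostrophes
  "|[\\p{L}\\p{N}](?:[\\p{L}\\p{N}'’-]*[\\p{L}\\p{N}])?",
  # any other non-space character stands alone
  "|\\S"
)

#' Tokenize a sentence
#'
#' Tokens cover all non-whitespace runs. Punctuation splits, except
#' word-internal hyphens and apostrophes (`JEAN-PIERRE`, `l'examen`), `@`
#' and dots inside email addresses, and `.`/`/`/`-` separators inside
#' numeric runs such as dates and dotted phone numbers.
#'
#' @param sentence_text Character scalar.
#' @return Data frame of token spans: `text`, `start`, `end` (0-based
#'   half-open, sentence-local), `start_char`, `end_char` (source offsets,
#'   `NA` until filled by [parse_document()]), `id` (0-based index).
#' @export
#' @examples
#' tokenize("12/03/2020, JEAN-PIERRE arrive")$text
tokenize <- function(sentence_text) {
  stopifnot(is.character(sentence_text), length(sentence_text) == 1L)
  if (is.na(sentence_text) || !nzchar(sentence_text)) return(empty_tokens())
  loc <- stringi::stri_locate_all_regex(sentence_text, TOKEN_PATTERN)[[1]]
  if (is.na(loc[1L, 1L])) return(empty_tokens())
  data.frame(
    text = stringi::stri_sub(sentence_text, loc[, 1L], loc[, 2L]),
    start = loc[, 1L] - 1L,
    end = loc[, 2L],
    start_char = NA_integer_,
    end_char = NA_integer_,
    id = seq_len(nrow(loc)) - 1L,
    stringsAsFactors = FALSE
  )
}

#' Parse a document into sentences with source offsets
#'
#' Runs [parse_html()], [split_sentences()] and [tokenize()] and threads
#' the offset map through, so every token carries both sentence-local
#' offsets and the position of its first/last character in the raw
#' document.
#'
#' @param doc A [source_document()].
#' @return List with `text`, `map` and `sentences` (list of [sentence()]
#'   objects).
#' @export
parse_document <- function(doc) {
  stopifnot(inherits(doc, "source_document"))
  parsed <- parse_html(doc$raw,
                       dialect = if (doc$dialect == "plain") "plain" else "html")
  sents <- split_sentences(parsed$text)
  out <- vector("list", nrow(sents))
  for (i in seq_len(nrow(sents))) {
    toks <- tokenize(sents$text[i])
    if (nrow(toks)) {
      gs <- sents$offset[i] + toks$start  # 0-based into extracted text
      ge <- sents$offset[i] + toks$end
      toks$start_char <- parsed$map$src_start[gs + 1L]
      toks$end_char <- parsed$map$src_end[ge]
    }
    out[[i]] <- sentence(sents$text[i], toks, doc_ref = doc$doc_id,
                         sent_index = i - 1L, text_offset = sents$offset[i])
  }
  list(text = parsed$text, map = parsed$map, sentences = out)
}
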