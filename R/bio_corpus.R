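# BIO encoding/decoding, sentence filtering, patient-level splitting, and
# the Prodigy-dialect JSONL / CoNLL readers and writers.

#' Construct a corpus record
#'
#' One annotated sentence together with its metadata, the unit stored in
#' JSONL files: the patient identifier (`ID_PAT`), the warehouse document
#' identifier (`ID_ENTREPOT`), the document-type code (`CODE`, carried as
#' an opaque string) and up to two annotator identifiers.
#'
#' @param sent A [sentence()].
#' @param mentions Mention data frame (non-overlapping).
#' @param meta Named list; missing fields default to `NA`.
#' @return An object of class `corpus_record`.
#' @export
corpus_record <- function(sent, mentions = entity_mentions(), meta = list()) {
  stopifnot(inherits(sent, "sentence"))
  defaults <- list(ID_PAT = NA_character_, ID_ENTREPOT = NA_character_,
                   CODE = NA_character_, annotator = NA_character_,
                   annotator2 = NA_character_)
  defaults[names(meta)] <- meta
  structure(list(sent = sent, mentions = mentions, meta = defaults),
            class = "corpus_record")
}

#' Encode mentions as BIO tags
#'
#' The first token of each mention receives `B-<category>`, subsequent
#' tokens `I-<category>`, all other tokens `O`.
#'
#' @param sent A [sentence()].
#' @param mentions Non-overlapping mention data frame.
#' @return Character vector of tags, one per token.
#' @export
#' @examples
#' s <- sentence("Monsieur le Docteur JEAN DUPONT")
#' bio_encode(s, annotate_sentence(s))
bio_encode <- function(sent, mentions) {
  n <- nrow(sent$tokens)
  tags <- rep("O", n)
  if (is.null(mentions) || nrow(mentions) == 0L) return(tags)
  for (k in seq_len(nrow(mentions))) {
    a <- mentions$token_first[k]; b <- mentions$token_last[k]
    if (a < 0L || b >= n) stop("mention token range outside sentence", call. = FALSE)
    if (any(tags[(a + 1L):(b + 1L)] != "O")) {
      stop("overlapping mentions cannot be BIO-encoded", call. = FALSE)
    }
    tags[a + 1L] <- paste0("B-", mentions$category[k])
    if (b > a) tags[(a + 2L):(b + 1L)] <- paste0("I-", mentions$category[k])
  }
  tags
}

#' Decode BIO tags into mentions
#'
#' Maximal `B-X I-X ...` runs become mentions. Invalid sequences are
#' repaired rather than rejected: an `I-X` not preceded by `B-X`/`I-X`
#' opens a new mention as if it were `B-X`.
#'
#' @param tags Character vector of BIO tags.
#' @param tokens Optional token data frame (as in `sentence()$tokens`);
#'   when supplied, char spans are filled in, otherwise they are `NA`.
#' @return Mention data frame.
#' @export
bio_decode <- function(tags, tokens = NULL) {
  n <- length(tags)
  cats <- ifelse(tags == "O", NA_character_, substring(tags, 3L))
  pre <- substring(tags, 1L, 1L)
  first <- integer(); last <- integer(); cat <- character()
  open_cat <- NA_character_; open_at <- NA_integer_
  close_run <- function(upto) {
    if (!is.na(open_cat)) {
      first <<- c(first, open_at); last <<- c(last, upto)
      cat <<- c(cat, open_cat)
    }
    open_cat <<- NA_character_
  }
  for (i in seq_len(n)) {
    if (is.na(cats[i])) {
      close_run(i - 2L)
    } else if (pre[i] == "B" || is.na(open_cat) || cats[i] != open_cat) {
      close_run(i - 2L)
      open_cat <- cats[i]; open_at <- i - 1L
    }
  }
  close_run(n - 1L)
  if (!length(first)) return(entity_mentions())
  cs <- ce <- rep(NA_integer_, length(first))
  if (!is.null(tokens) && nrow(tokens)) {
    cs <- tokens$start[first + 1L]
    ce <- tokens$end[last + 1L]
  }
  entity_mentions(category = cat, token_first = first, token_last = last,
                  char_start = cs, char_end = ce, source = "manual",
                  rule_id = "bio-decode")
}

#' Keep only sentences that contain at least one mention
#'
#' @param corpus List of [corpus_record()] objects.
#' @return Filtered list; idempotent.
#' @export
filter_sentences <- function(corpus) {
  Filter(function(r) nrow(r$mentions) > 0L, corpus)
}

# 32-bit arithmetic on doubles (R integers are signed 32-bit).
mul32 <- function(a, b) {
  lo <- a %% 65536; hi <- a %/% 65536
  ((lo * b) %% 4294967296 + ((hi * b) %% 65536) * 65536) %% 4294967296
}
xor32 <- function(a, b) {
  bitwXor(a %% 65536, b %% 65536) +
    bitwXor(a %/% 65536, b %/% 65536) * 65536
}
shr32 <- function(a, k) a %/% 2^k

# Deterministic, session-independent hash of a string to [0, 1):
# FNV-1a over the UTF-8 bytes followed by the MurmurHash3 finalizer.
string_hash01 <- function(x) {
  vapply(x, function(s) {
    h <- 2166136261
    for (byte in utf8ToInt(enc2utf8(s))) {
      h <- xor32(h, byte %% 256)
      h <- mul32(h, 16777619)
    }
    h <- xor32(h, shr32(h, 16)); h <- mul32(h, 2246822507)
    h <- xor32(h, shr32(h, 13)); h <- mul32(h, 3266489909)
    h <- xor32(h, shr32(h, 16))
    h / 4294967296
  }, numeric(1), USE.NAMES = FALSE)
}

#' Patient-level train/validation/test split
#'
#' Every patient (and therefore every document of that patient) is
#' assigned to exactly one partition. Assignment is by a stable hash of
#' the patient identifier salted with the seed, so it is reproducible
#' without storing state and a patient's partition does not change when
#' other patients are added or removed.
#'
#' @param patient_ids Character vector of patient identifiers (duplicates
#'   allowed; e.g. one entry per document).
#' @param ratios Numeric vector of three partition ratios summing to 1.
#' @param seed Integer salt.
#' @return An object of class `split_assignment`: a named character vector
#'   mapping each distinct patient to `"train"`, `"valid"` or `"test"`,
#'   with `ratios` and `seed` attributes.
#' @export
#' @examples
#' split_by_patient(c("p1", "p2", "p3"), seed = 42)
split_by_patient <- function(patient_ids, ratios = c(0.8, 0.1, 0.1),
                             seed = 42L) {
  if (length(ratios) != 3L || any(ratios < 0) ||
      abs(sum(ratios) - 1) > 1e-8) {
    stop("ratios must be three non-negative numbers summing to 1",
         call. = FALSE)
  }
  patients <- unique(as.character(patient_ids))
  u <- string_hash01(paste0(seed, ":", patients))
  cuts <- cumsum(ratios)
  part <- ifelse(u < cuts[1L], "train", ifelse(u < cuts[2L], "valid", "test"))
  names(part) <- patients
  structure(part, ratios = ratios, seed = seed, class = "split_assignment")
}

#' Per-class mention statistics of a corpus
#'
#' Sentence count, per-category mention counts and each category's share
#' of all mentions as a percentage rounded half-up to one decimal.
#'
#' @param corpus List of [corpus_record()] objects.
#' @return List with `n_sentences`, `counts` (named integer vector over
#'   [pii_categories()]) and `shares` (named numeric, percentages).
#' @export
corpus_stats <- function(corpus) {
  cats <- unlist(lapply(corpus, function(r) r$mentions$category),
                 use.names = FALSE)
  counts <- table(factor(cats, levels = pii_categories()))
  counts <- stats::setNames(as.integer(counts), pii_categories())
  list(n_sentences = length(corpus), counts = counts,
       shares = category_shares(counts))
}

#' Percentage share of each category
#'
#' @param counts Named numeric vector of per-category mention counts.
#' @param digits Decimals kept (half-up rounding).
#' @return Named numeric vector of percentages.
#' @export
#' @examples
#' category_shares(c(DATE = 272, DOCTOR = 214, PATIENT = 514))
category_shares <- function(counts, digits = 1L) {
  total <- sum(counts)
  if (total == 0) return(counts * 0)
  round_half_up(100 * counts / total, digits)
}

#' Round half away from zero
#'
#' Fixed-convention rounding (0.05 at one decimal rounds to 0.1),
#' independent of the banker's rounding of base [round()].
#'
#' @param x Numeric vector.
#' @param digits Number of decimals.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

record_to_json <- function(r) {
  toks <- r$sent$tokens
  obj <- list(
    text = jsonlite::unbox(r$sent$text),
    meta = lapply(r$meta, jsonlite::unbox),
    tokens_parser = data.frame(
      start_char = toks$start_char, end_char = toks$end_char,
      text = toks$text, start = toks$start, end = toks$end, id = toks$id,
      stringsAsFactors = FALSE
    )
  )
  if (nrow(r$mentions)) {
    obj$spans <- data.frame(start = r$mentions$char_start,
                            end = r$mentions$char_end,
                            label = r$mentions$category,
                            stringsAsFactors = FALSE)
  } else {
    obj$spans <- data.frame()
  }
  jsonlite::toJSON(obj, dataframe = "rows", na = "null", digits = NA)
}

#' Write a corpus as Prodigy-dialect JSONL
#'
#' One JSON object per line with fields `text`, `meta`
#' (`ID_PAT`, `ID_ENTREPOT`, `CODE`, `annotator`, `annotator2`),
#' `tokens_parser` (per-token `start_char`, `end_char`, `text`, `start`,
#' `end`, `id`) and `spans` (`start`, `end`, `label`, sentence-local
#' half-open character offsets).
#'
#' @param corpus List of [corpus_record()] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_jsonl <- function(corpus, path) {
  lines <- vapply(corpus, function(r) as.character(record_to_json(r)),
                  character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(lines)) writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

#' Read a Prodigy-dialect JSONL corpus
#'
#' Inverse of [write_jsonl()]: `read_jsonl()` then `write_jsonl()`
#' reproduces the file.
#'
#' @param path Input file path.
#' @return List of [corpus_record()] objects.
#' @export
read_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  lapply(seq_along(lines), function(i) {
    obj <- tryCatch(
      jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
      error = function(e) {
        stop("malformed JSONL at line ", i, ": ", conditionMessage(e),
             call. = FALSE)
      }
    )
    toks <- obj$tokens_parser
    if (is.null(toks) || !length(toks)) {
      toks <- empty_tokens()
    } else {
      toks <- data.frame(text = as.character(toks$text),
                         start = as.integer(toks$start),
                         end = as.integer(toks$end),
                         start_char = as.integer(toks$start_char),
                         end_char = as.integer(toks$end_char),
                         id = as.integer(toks$id),
                         stringsAsFactors = FALSE)
    }
    sent <- sentence(obj$text, toks)
    mentions <- entity_mentions()
    sp <- obj$spans
    if (!is.null(sp) && length(sp) && nrow(sp)) {
      tf <- vapply(sp$start, function(a) match(TRUE, toks$start >= a) - 1L,
                   integer(1))
      tl <- vapply(sp$end, function(b) {
        max(which(toks$end <= b)) - 1L
      }, integer(1))
      mentions <- entity_mentions(
        category = as.character(sp$label),
        token_first = tf, token_last = tl,
        char_start = as.integer(sp$start), char_end = as.integer(sp$end),
        source = "manual", rule_id = "bio-decode"
      )
    }
    meta <- lapply(as.list(obj$meta),
                   function(v) if (is.null(v) || !length(v)) NA else v)
    corpus_record(sent, mentions, meta)
  })
}

#' Write a corpus in CoNLL form
#'
#' One `token<TAB>tag` line per token, a blank line between sentences.
#'
#' @param corpus List of [corpus_record()] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_conll <- function(corpus, path) {
  blocks <- vapply(corpus, function(r) {
    tags <- bio_encode(r$sent, r$mentions)
    paste(paste(r$sent$tokens$text, tags, sep = "\t"), collapse = "\n")
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(blocks, collapse = "\n\n"), con, useBytes = TRUE)
  invisible(path)
}

#' Read a CoNLL file back into token/tag frames
#'
#' @param path Input file path.
#' @return List of data frames with columns `token`, `tag`.
#' @export
read_conll <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  groups <- split(lines, cumsum(!nzchar(lines)))
  groups <- lapply(groups, function(g) g[nzchar(g)])
  groups <- Filter(length, groups)
  unname(lapply(groups, function(g) {
    parts <- strsplit(g, "\t", fixed = TRUE)
    data.frame(token = vapply(parts, `[`, "", 1L),
               tag = vapply(parts, `[`, "", 2L),
               stringsAsFactors = FALSE)
  }))
}
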