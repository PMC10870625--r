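# Rule- and gazetteer-based PII detectors. Each detector maps a sentence to
# stand-off mentions; annotate_sentence() runs the cascade and resolves
# overlaps into a single non-overlapping mention set.

FRENCH_MONTHS <- c("JANVIER", "FEVRIER", "MARS", "AVRIL", "MAI", "JUIN",
                   "JUILLET", "AOUT", "SEPTEMBRE", "OCTOBRE", "NOVEMBRE",
                   "DECEMBRE")
FRENCH_MONTH_ABBR <- c("JANV", "FEVR", "FEV", "AVR", "JUIL", "SEPT", "OCT",
                       "NOV", "DEC")
FRENCH_DAYS <- c("LUNDI", "MARDI", "MERCREDI", "JEUDI", "VENDREDI",
                 "SAMEDI", "DIMANCHE")

#' Rule configuration for the detector cascade
#'
#' Bundles the pattern lists, lexicons and windows used by the detectors.
#' Defaults cover the classic lexical forms of French clinical reports:
#' numeric dates (`dd/mm/yyyy`, `dd-mm-yyyy`, `dd.mm.yyyy`, `dd/mm/yy`,
#' `yyyy-mm-dd`), lexical dates with French month names and abbreviations,
#' phone numbers as 3 to 6 two-digit groups or a contiguous 10-digit run,
#' 5-digit postal codes, street cue words plus their abbreviation
#' expansions, and practitioner role triggers.
#'
#' @param context_window Token distance for contextual cues (role trigger
#'   to name, postal code to city).
#' @param priority Category order used to break ties when overlapping
#'   detections have equal span length; must be a permutation of
#'   [pii_categories()].
#' @param street_cues,role_triggers,month_lexicon Normalized lexicons;
#'   defaults are built from the bundled vocabulary and
#'   [abbreviation_table()].
#' @param date_formats `strftime` formats used to render known birthdates
#'   when hunting metadata echoes.
#' @return An object of class `rule_config`.
#' @export
rule_config <- function(context_window = 4L,
                        priority = c("PATIENT", "DOCTOR", "EMAIL", "PHONE",
                                     "DATE", "STR", "ZIP", "VILLE"),
                        street_cues = NULL, role_triggers = NULL,
                        month_lexicon = NULL,
                        date_formats = c("%d/%m/%Y", "%d-%m-%Y", "%d.%m.%Y",
                                         "%d/%m/%y", "%Y-%m-%d")) {
  if (!setequal(priority, pii_categories()) ||
      length(priority) != length(pii_categories())) {
    stop("priority must be a permutation of the eight PII categories",
         call. = FALSE)
  }
  abbr <- abbreviation_table()
  if (is.null(street_cues)) {
    street_cues <- unique(c(
      "RUE", "AVENUE", "BOULEVARD", "ALLEE", "PLACE", "CHEMIN", "IMPASSE",
      "ROUTE", "QUAI", "SQUARE", "FAUBOURG", "COURS", "PASSAGE",
      normalize_term(abbr$abbrev[abbr$role == "expansion"])
    ))
  }
  if (is.null(role_triggers)) {
    role_triggers <- unique(c(
      "DR", "DOCTEUR", "PR", "PROFESSEUR", "PROF",
      normalize_term(abbr$abbrev[abbr$role == "role-marker"])
    ))
  }
  if (is.null(month_lexicon)) {
    month_lexicon <- c(FRENCH_MONTHS, FRENCH_MONTH_ABBR)
  }
  structure(
    list(
      date_numeric = "^(\\d{1,2})([/.–-])(\\d{1,2})\\2(\\d{4}|\\d{2})$",
      date_iso = "^(\\d{4})-(\\d{1,2})-(\\d{1,2})$",
      phone_token = "^\\d{2}(?:[.–-]\\d{2}){2,5}$",
      phone_digits = "^0\\d{9}$",
      phone_groups = c(3L, 6L),
      zip_pattern = "^\\d{5}$",
      email_pattern = paste0("^[\\p{L}\\p{N}][\\p{L}\\p{N}._%+-]*@",
                             "[\\p{L}\\p{N}-]+(?:\\.[\\p{L}\\p{N}-]+)*",
                             "\\.\\p{L}{2,}$"),
      street_cues = street_cues,
      role_triggers = role_triggers,
      month_lexicon = month_lexicon,
      day_lexicon = FRENCH_DAYS,
      context_window = as.integer(context_window),
      priority = priority,
      date_formats = date_formats
    ),
    class = "rule_config"
  )
}

is_capitalized <- function(x) {
  stringi::stri_detect_regex(x, "^\\p{Lu}")
}

STOP_CONTINUATION <- c("DE", "DU", "DES", "LE", "LA", "L", "D")

# Tokens that are masking placeholders ("[DOCTOR]" tokenizes to three
# tokens); excluded from name candidates so masked documents re-annotate
# to nothing and masking is idempotent.
is_placeholder_token <- function(toks) {
  n <- nrow(toks)
  out <- rep(FALSE, n)
  cand <- which(toks$text %in% pii_categories())
  for (i in cand) {
    if (i > 1L && i < n && toks$text[i - 1L] == "[" &&
        toks$text[i + 1L] == "]") {
      out[i] <- TRUE
    }
  }
  out
}

#' Detect date mentions
#'
#' Numeric dates in the `dd/mm/yyyy` family (separators `/`, `-`, `.`,
#' two- or four-digit year, day and month bounds validated) and the ISO
#' `yyyy-mm-dd` form, plus lexical dates: optional day name, day number,
#' French month word or abbreviation, optional four-digit year.
#'
#' @param sent A [sentence()].
#' @param cfg A [rule_config()].
#' @return Mention data frame (category `DATE`).
#' @export
detect_dates <- function(sent, cfg = rule_config()) {
  toks <- sent$tokens
  n <- nrow(toks)
  if (n == 0L) return(entity_mentions())
  out <- list()
  # numeric single-token dates
  m <- stringi::stri_match_first_regex(toks$text, cfg$date_numeric)
  ok <- !is.na(m[, 1L])
  if (any(ok)) {
    d <- suppressWarnings(as.integer(m[ok, 2L]))
    mo <- suppressWarnings(as.integer(m[ok, 4L]))
    valid <- d >= 1L & d <= 31L & mo >= 1L & mo <= 12L
    idx <- which(ok)[valid]
    out[[length(out) + 1L]] <-
      mentions_from_tokens(toks, "DATE", idx - 1L, idx - 1L,
                           "pattern", "date-numeric")
  }
  mi <- stringi::stri_match_first_regex(toks$text, cfg$date_iso)
  oki <- !is.na(mi[, 1L])
  if (any(oki)) {
    mo <- suppressWarnings(as.integer(mi[oki, 3L]))
    d <- suppressWarnings(as.integer(mi[oki, 4L]))
    valid <- d >= 1L & d <= 31L & mo >= 1L & mo <= 12L
    idx <- which(oki)[valid]
    out[[length(out) + 1L]] <-
      mentions_from_tokens(toks, "DATE", idx - 1L, idx - 1L,
                           "pattern", "date-iso")
  }
  # lexical dates: [day-name] day-number month-word [year]
  norm <- normalize_term(toks$text)
  is_day_num <- stringi::stri_detect_regex(toks$text, "^(\\d{1,2}|1ER|1er)$") &
    suppressWarnings(as.integer(stringi::stri_extract_first_regex(toks$text, "\\d+"))) >= 1L &
    suppressWarnings(as.integer(stringi::stri_extract_first_regex(toks$text, "\\d+"))) <= 31L
  is_month <- norm %in% cfg$month_lexicon
  is_year <- stringi::stri_detect_regex(toks$text, "^\\d{4}$")
  i <- 1L
  while (i < n) {
    if (isTRUE(is_day_num[i]) && isTRUE(is_month[i + 1L])) {
      first <- i
      if (i > 1L && norm[i - 1L] %in% cfg$day_lexicon) first <- i - 1L
      last <- i + 1L
      if (last < n && isTRUE(is_year[last + 1L])) last <- last + 1L
      out[[length(out) + 1L]] <-
        mentions_from_tokens(toks, "DATE", first - 1L, last - 1L,
                             "pattern", "date-lexical")
      i <- last + 1L
    } else {
      i <- i + 1L
    }
  }
  do.call(rbind, c(list(entity_mentions()), out))
}

#' Detect phone/fax mentions
#'
#' Matches a contiguous 10-digit token starting with 0, a single token of
#' dot/dash-separated two-digit groups, and runs of 3 to 6 consecutive
#' two-digit tokens (the space-separated format).
#'
#' @inheritParams detect_dates
#' @return Mention data frame (category `PHONE`).
#' @export
detect_phone <- function(sent, cfg = rule_config()) {
  toks <- sent$tokens
  n <- nrow(toks)
  if (n == 0L) return(entity_mentions())
  out <- list()
  single <- which(stringi::stri_detect_regex(toks$text, cfg$phone_digits) |
                    stringi::stri_detect_regex(toks$text, cfg$phone_token))
  if (length(single)) {
    out[[length(out) + 1L]] <-
      mentions_from_tokens(toks, "PHONE", single - 1L, single - 1L,
                           "pattern", "phone-token")
  }
  # runs of consecutive two-digit tokens
  is_pair <- stringi::stri_detect_regex(toks$text, "^\\d{2}$")
  i <- 1L
  lo <- cfg$phone_groups[1L]; hi <- cfg$phone_groups[2L]
  while (i <= n) {
    if (is_pair[i]) {
      j <- i
      while (j < n && is_pair[j + 1L]) j <- j + 1L
      len <- j - i + 1L
      if (len >= lo && len <= hi) {
        out[[length(out) + 1L]] <-
          mentions_from_tokens(toks, "PHONE", i - 1L, j - 1L,
                               "pattern", "phone-groups")
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  do.call(rbind, c(list(entity_mentions()), out))
}

#' Detect postal-code mentions
#'
#' A standalone five-digit token becomes a `ZIP` mention when it is listed
#' in the postal-code gazetteer or sits within `context_window` tokens of
#' a city-gazetteer hit or a street cue.
#'
#' @inheritParams detect_dates
#' @param gaz_zip Postal-code [gazetteer()] (may be `NULL`).
#' @param gaz_ville City gazetteer used for the contextual route (may be
#'   `NULL`).
#' @return Mention data frame (category `ZIP`).
#' @export
detect_zip <- function(sent, cfg = rule_config(), gaz_zip = NULL,
                       gaz_ville = NULL) {
  toks <- sent$tokens
  n <- nrow(toks)
  if (n == 0L) return(entity_mentions())
  cand <- which(stringi::stri_detect_regex(toks$text, cfg$zip_pattern))
  if (!length(cand)) return(entity_mentions())
  norm <- normalize_term(toks$text)
  ctx_support <- gaz_has(gaz_ville, norm) | norm %in% cfg$street_cues
  w <- cfg$context_window
  keep <- vapply(cand, function(i) {
    if (gaz_has(gaz_zip, norm[i])) return(TRUE)
    lo <- max(1L, i - w); hi <- min(n, i + w)
    any(ctx_support[lo:hi])
  }, logical(1))
  src <- ifelse(gaz_has(gaz_zip, norm[cand[keep]]), "gazetteer", "context")
  mentions_from_tokens(toks, "ZIP", cand[keep] - 1L, cand[keep] - 1L,
                       src, "zip")
}

#' Detect email mentions
#'
#' @inheritParams detect_dates
#' @return Mention data frame (category `EMAIL`).
#' @export
detect_email <- function(sent, cfg = rule_config()) {
  toks <- sent$tokens
  if (nrow(toks) == 0L) return(entity_mentions())
  hit <- which(stringi::stri_detect_regex(toks$text, cfg$email_pattern))
  mentions_from_tokens(toks, "EMAIL", hit - 1L, hit - 1L, "pattern", "email")
}

#' Detect street-address mentions
#'
#' A street cue word (`RUE`, `AVENUE`, ... or an abbreviation expansion)
#' anchors a mention extending over an optional leading house number and
#' the following capitalized tokens, with French articles allowed inside
#' the run. A cue with no capitalized continuation (e.g. lowercase prose
#' "il continue sa rue") yields nothing unless the token run continues a
#' gazetteer entry.
#'
#' @inheritParams detect_dates
#' @param gaz_str Street-name [gazetteer()] (may be `NULL`).
#' @return Mention data frame (category `STR`).
#' @export
detect_street <- function(sent, cfg = rule_config(), gaz_str = NULL) {
  toks <- sent$tokens
  n <- nrow(toks)
  if (n == 0L) return(entity_mentions())
  norm <- normalize_term(toks$text)
  caps <- is_capitalized(toks$text)
  out <- list()
  i <- 1L
  while (i <= n) {
    if (norm[i] %in% cfg$street_cues) {
      first <- i
      if (i > 1L && stringi::stri_detect_regex(toks$text[i - 1L], "^\\d{1,4}$")) {
        first <- i - 1L
      }
      # capitalisation-driven continuation
      j <- i
      while (j < n && (caps[j + 1L] || norm[j + 1L] %in% STOP_CONTINUATION)) {
        j <- j + 1L
      }
      while (j > i && !caps[j]) j <- j - 1L  # never end on an article
      cap_ok <- j > i
      # gazetteer-driven continuation (handles lowercase addresses)
      gaz_j <- i
      if (!is.null(gaz_str) && length(gaz_str$multiword)) {
        for (len in seq(from = min(gaz_str$max_words, n - i + 1L), to = 2L)) {
          if (len < 2L) break
          phrase <- paste(norm[i:(i + len - 1L)], collapse = " ")
          if (phrase %in% gaz_str$entries) { gaz_j <- i + len - 1L; break }
        }
      }
      last <- max(if (cap_ok) j else i, gaz_j)
      if (last > i) {
        out[[length(out) + 1L]] <-
          mentions_from_tokens(toks, "STR", first - 1L, last - 1L,
                               if (gaz_j > i) "gazetteer" else "pattern",
                               "street-cue")
        i <- last + 1L
        next
      }
    }
    i <- i + 1L
  }
  do.call(rbind, c(list(entity_mentions()), out))
}

#' Detect city mentions
#'
#' Longest gazetteer match over token runs. Capitalized matches stand on
#' their own; lowercase matches additionally require an adjacent postal
#' code or street cue within `context_window` tokens.
#'
#' @inheritParams detect_dates
#' @param gaz_ville City [gazetteer()].
#' @return Mention data frame (category `VILLE`).
#' @export
detect_city <- function(sent, cfg = rule_config(), gaz_ville = NULL) {
  toks <- sent$tokens
  n <- nrow(toks)
  if (n == 0L || is.null(gaz_ville) || !length(gaz_ville$entries)) {
    return(entity_mentions())
  }
  norm <- normalize_term(toks$text)
  caps <- is_capitalized(toks$text)
  is_word <- stringi::stri_detect_regex(toks$text, "^\\p{L}")
  zip_like <- stringi::stri_detect_regex(toks$text, cfg$zip_pattern)
  cue_like <- norm %in% cfg$street_cues
  w <- cfg$context_window
  out <- list()
  i <- 1L
  while (i <= n) {
    if (is_word[i]) {
      hit_len <- 0L
      for (len in seq(from = min(gaz_ville$max_words, n - i + 1L), to = 1L)) {
        phrase <- paste(norm[i:(i + len - 1L)], collapse = " ")
        if (phrase %in% gaz_ville$entries) { hit_len <- len; break }
      }
      if (hit_len > 0L) {
        j <- i + hit_len - 1L
        all_caps <- all(caps[i:j])
        lo <- max(1L, i - w); hi <- min(n, j + w)
        supported <- any(zip_like[lo:hi]) || any(cue_like[lo:hi])
        if (all_caps || supported) {
          out[[length(out) + 1L]] <-
            mentions_from_tokens(toks, "VILLE", i - 1L, j - 1L,
                                 "gazetteer", "city")
          i <- j + 1L
          next
        }
      }
    }
    i <- i + 1L
  }
  do.call(rbind, c(list(entity_mentions()), out))
}

#' Detect practitioner-name mentions
#'
#' Two routes: (a) a role trigger (`Dr`, `Docteur`, `Pr`, `Professeur`,
#' case-insensitive) followed within `context_window` tokens by
#' capitalized tokens yields a `DOCTOR` mention over those tokens, title
#' excluded, regardless of the gazetteer; (b) capitalized tokens whose
#' normalized form is in the practitioner gazetteer, consecutive hits
#' merged (given name + surname).
#'
#' @inheritParams detect_dates
#' @param gaz_doc Practitioner-name [gazetteer()] (may be `NULL`).
#' @return Mention data frame (category `DOCTOR`).
#' @export
detect_doctor <- function(sent, cfg = rule_config(), gaz_doc = NULL) {
  toks <- sent$tokens
  n <- nrow(toks)
  if (n == 0L) return(entity_mentions())
  norm <- normalize_term(toks$text)
  caps <- is_capitalized(toks$text) & !is_placeholder_token(toks)
  is_trigger <- norm %in% cfg$role_triggers
  out <- list()
  # (a) role-trigger route
  for (t in which(is_trigger)) {
    hi <- min(n, t + cfg$context_window)
    j <- t + 1L
    start <- NA_integer_
    while (j <= hi) {
      if (caps[j] && !is_trigger[j]) { start <- j; break }
      j <- j + 1L
    }
    if (is.na(start)) next
    end <- start
    while (end < n && caps[end + 1L] && !is_trigger[end + 1L]) end <- end + 1L
    out[[length(out) + 1L]] <-
      mentions_from_tokens(toks, "DOCTOR", start - 1L, end - 1L,
                           "context", "doctor-trigger")
  }
  # (b) gazetteer route
  if (!is.null(gaz_doc) && length(gaz_doc$entries)) {
    hit <- caps & gaz_has(gaz_doc, norm) & !is_trigger
    i <- 1L
    while (i <= n) {
      if (hit[i]) {
        j <- i
        while (j < n && hit[j + 1L]) j <- j + 1L
        out[[length(out) + 1L]] <-
          mentions_from_tokens(toks, "DOCTOR", i - 1L, j - 1L,
                               "gazetteer", "doctor-gazetteer")
        i <- j + 1L
      } else {
        i <- i + 1L
      }
    }
  }
  do.call(rbind, c(list(entity_mentions()), out))
}

#' Build metadata keys for one patient record
#'
#' Derives, deterministically, the normalized name-part set
#' (compound-expanded, ambiguity-filtered) and the birthdate rendered in
#' every configured date format, ready for [detect_patient()].
#'
#' @param doc A [source_document()] whose metadata carries
#'   `patient_first_name`, `patient_last_name` and optionally `birthdate`.
#' @param cfg A [rule_config()].
#' @param stop_set,min_len Ambiguity filtering of name parts.
#' @return An object of class `patient_keys`.
#' @export
patient_record_keys <- function(doc, cfg = rule_config(),
                                stop_set = default_stop_set(), min_len = 2L) {
  md <- if (inherits(doc, "source_document")) doc$metadata else doc
  raw_names <- c(md$patient_first_name, md$patient_last_name)
  raw_names <- raw_names[!is.na(raw_names) & nzchar(raw_names)]
  words <- unlist(strsplit(normalize_term(raw_names), " ", fixed = TRUE))
  parts <- filter_ambiguous(expand_compound(words), stop_set, min_len)
  birth_tokens <- character()
  birth_lexical <- NULL
  if (!is.null(md$birthdate) && !is.na(md$birthdate)) {
    bd <- as.Date(md$birthdate)
    birth_tokens <- unique(vapply(cfg$date_formats, function(f) format(bd, f),
                                  character(1)))
    mo <- as.integer(format(bd, "%m"))
    birth_lexical <- c(as.character(as.integer(format(bd, "%d"))),
                       FRENCH_MONTHS[mo], format(bd, "%Y"))
  }
  structure(list(name_parts = parts, birth_tokens = birth_tokens,
                 birth_lexical = birth_lexical),
            class = "patient_keys")
}

#' Detect patient-name and birthdate echoes
#'
#' Case- and accent-insensitive token matches against the patient's known
#' name parts become `PATIENT` mentions (consecutive matches merged);
#' occurrences of the known birthdate in any configured numeric format, or
#' as a day/month-word/year token triple, become `DATE` mentions. Without
#' metadata keys nothing is detected.
#'
#' @param sent A [sentence()].
#' @param keys A `patient_keys` object from [patient_record_keys()].
#' @return Mention data frame (categories `PATIENT` and `DATE`).
#' @export
detect_patient <- function(sent, keys) {
  toks <- sent$tokens
  n <- nrow(toks)
  if (n == 0L || is.null(keys)) return(entity_mentions())
  norm <- normalize_term(toks$text)
  out <- list()
  if (length(keys$name_parts)) {
    hit <- norm %in% keys$name_parts
    i <- 1L
    while (i <= n) {
      if (hit[i]) {
        j <- i
        while (j < n && hit[j + 1L]) j <- j + 1L
        out[[length(out) + 1L]] <-
          mentions_from_tokens(toks, "PATIENT", i - 1L, j - 1L,
                               "metadata", "patient-name")
        i <- j + 1L
      } else {
        i <- i + 1L
      }
    }
  }
  if (length(keys$birth_tokens)) {
    bd <- which(toks$text %in% keys$birth_tokens)
    if (length(bd)) {
      out[[length(out) + 1L]] <-
        mentions_from_tokens(toks, "DATE", bd - 1L, bd - 1L,
                             "metadata", "birthdate")
    }
  }
  if (!is.null(keys$birth_lexical) && n >= 3L) {
    for (i in seq_len(n - 2L)) {
      if (toks$text[i] == keys$birth_lexical[1L] &&
          norm[i + 1L] == keys$birth_lexical[2L] &&
          toks$text[i + 2L] == keys$birth_lexical[3L]) {
        out[[length(out) + 1L]] <-
          mentions_from_tokens(toks, "DATE", i - 1L, i + 1L,
                               "metadata", "birthdate-lexical")
      }
    }
  }
  do.call(rbind, c(list(entity_mentions()), out))
}

#' Resolve overlapping mentions
#'
#' Greedy longest-span-first resolution; ties on span length are broken by
#' the configured category priority, then by position. The result is
#' non-overlapping and sorted by start offset.
#'
#' @param mentions Mention data frame (possibly overlapping).
#' @param priority Category priority order (first wins ties).
#' @return Non-overlapping mention data frame sorted by `char_start`.
#' @export
resolve_overlaps <- function(mentions,
                             priority = rule_config()$priority) {
  if (nrow(mentions) <= 1L) return(mentions)
  prank <- match(mentions$category, priority)
  len <- mentions$char_end - mentions$char_start
  ord <- order(-len, prank, mentions$char_start)
  mentions <- mentions[ord, , drop = FALSE]
  kept <- logical(nrow(mentions))
  occ_start <- integer(0)
  occ_end <- integer(0)
  for (k in seq_len(nrow(mentions))) {
    a <- mentions$char_start[k]; b <- mentions$char_end[k]
    if (!any(a < occ_end & b > occ_start)) {
      kept[k] <- TRUE
      occ_start <- c(occ_start, a)
      occ_end <- c(occ_end, b)
    }
  }
  res <- mentions[kept, , drop = FALSE]
  res <- res[order(res$char_start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Annotate one sentence with the full detector cascade
#'
#' Runs every detector (patterns, gazetteers, metadata echoes), pools the
#' candidate mentions and resolves overlaps with
#' [resolve_overlaps()]. Deterministic: identical input and configuration
#' give identical output.
#'
#' @param sent A [sentence()].
#' @param cfg A [rule_config()].
#' @param gazetteers Named list with any of `DOCTOR`, `STR`, `ZIP`,
#'   `VILLE` [gazetteer()] objects (missing ones disable the lookup
#'   route).
#' @param keys Optional `patient_keys` from [patient_record_keys()].
#' @return Non-overlapping, sorted mention data frame.
#' @export
#' @examples
#' s <- sentence("Monsieur le Docteur JEAN DUPONT")
#' annotate_sentence(s)
annotate_sentence <- function(sent, cfg = rule_config(),
                              gazetteers = list(), keys = NULL) {
  cand <- rbind(
    detect_patient(sent, keys),
    detect_doctor(sent, cfg, gazetteers$DOCTOR),
    detect_email(sent, cfg),
    detect_phone(sent, cfg),
    detect_dates(sent, cfg),
    detect_street(sent, cfg, gazetteers$STR),
    detect_zip(sent, cfg, gazetteers$ZIP, gazetteers$VILLE),
    detect_city(sent, cfg, gazetteers$VILLE)
  )
  resolve_overlaps(cand, cfg$priority)
}
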