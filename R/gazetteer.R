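# Normalised dictionaries for lookup-based detection: streets, postal
# codes and cities from files in the Base Adresse Nationale column schema,
# practitioner names from files in the Health Directory schema.

#' Default ambiguous-term stop set
#'
#' French articles and contracted prepositions that occur inside person and
#' street names but are far too common as ordinary words to be dictionary
#' entries on their own, extended with all single letters.
#'
#' @return Character vector of normalized stop terms.
#' @export
default_stop_set <- function() {
  unique(c("DE", "DU", "DES", "LE", "LA", "L", "D", LETTERS))
}

#' Normalize a dictionary term
#'
#' Uppercases, strips diacritics and collapses internal whitespace; the
#' same normalization is applied to tokens at match time, making all
#' dictionary matching case- and accent-insensitive (directory files and
#' clinical text routinely disagree on accents).
#'
#' @param term Character vector.
#' @return Normalized character vector; idempotent.
#' @export
#' @examples
#' normalize_term("Évreux")
#' normalize_term("  la  paix ")
normalize_term <- function(term) {
  x <- stringi::stri_trans_general(term, "Latin-ASCII")
  x <- stringi::stri_trans_toupper(x)
  x <- stringi::stri_replace_all_regex(x, "\\s+", " ")
  stringi::stri_trim_both(x)
}

#' Expand a compound name into its parts
#'
#' Compound given names and surnames appear both whole and as single parts
#' in clinical text, so the dictionary is augmented with every
#' hyphen-separated part alongside the full form: `"JEAN-PIERRE"` yields
#' `"JEAN-PIERRE"`, `"JEAN"` and `"PIERRE"`.
#'
#' @param name Character vector of names.
#' @return Character vector of unique names plus parts.
#' @export
expand_compound <- function(name) {
  name <- name[!is.na(name) & nzchar(name)]
  if (!length(name)) return(character())
  parts <- unlist(strsplit(name, "-", fixed = TRUE), use.names = FALSE)
  unique(c(name, parts[nzchar(parts)]))
}

#' Remove ambiguous and too-short entries
#'
#' @param entries Character vector of normalized entries.
#' @param stop_set Normalized terms to exclude (default
#'   [default_stop_set()]).
#' @param min_len Minimum entry length in characters (default 2).
#' @return Filtered character vector; idempotent.
#' @export
#' @examples
#' filter_ambiguous(c("DE", "DUPONT"))
filter_ambiguous <- function(entries, stop_set = default_stop_set(),
                             min_len = 2L) {
  entries <- entries[!is.na(entries)]
  entries[!(entries %in% stop_set) & nchar(entries) >= min_len]
}

#' Construct a gazetteer
#'
#' @param category PII category the gazetteer detects.
#' @param entries Character vector of terms (normalized internally).
#' @param stop_set,min_len Passed to [filter_ambiguous()].
#' @return An object of class `gazetteer` with single-token and multiword
#'   entry sets.
#' @export
gazetteer <- function(category, entries, stop_set = default_stop_set(),
                      min_len = 2L) {
  assert_category(category)
  entries <- filter_ambiguous(unique(normalize_term(entries)), stop_set, min_len)
  structure(
    list(category = category,
         entries = entries,
         multiword = entries[grepl(" ", entries, fixed = TRUE)],
         max_words = if (length(entries)) {
           max(stringi::stri_count_fixed(entries, " ")) + 1L
         } else 1L,
         min_len = as.integer(min_len)),
    class = "gazetteer"
  )
}

#' @export
print.gazetteer <- function(x, ...) {
  cat("<gazetteer> ", x$category, ": ", length(x$entries), " entries (",
      length(x$multiword), " multiword)\n", sep = "")
  invisible(x)
}

gaz_has <- function(gaz, term) {
  if (is.null(gaz) || !length(gaz$entries)) return(rep(FALSE, length(term)))
  term %in% gaz$entries
}

# Auto-detect the delimiter of a one-header-line CSV/TSV file.
detect_delim <- function(path) {
  header <- readLines(path, n = 1L, encoding = "UTF-8", warn = FALSE)
  counts <- vapply(c(",", ";", "\t"),
                   function(d) stringi::stri_count_fixed(header, d), integer(1))
  names(counts)[which.max(counts)]
}

read_delim_file <- function(path, required_cols) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  delim <- detect_delim(path)
  df <- utils::read.table(path, header = TRUE, sep = delim, quote = "\"",
                          fileEncoding = "UTF-8", stringsAsFactors = FALSE,
                          check.names = FALSE, comment.char = "")
  missing <- setdiff(required_cols, names(df))
  if (length(missing)) {
    stop("schema error in ", basename(path), ": missing column(s) ",
         paste(sprintf("'%s'", missing), collapse = ", "), call. = FALSE)
  }
  df
}

#' Load street/zip/city gazetteers from a BAN-schema file
#'
#' Expects a delimited file (delimiter auto-detected among `,`, `;`, tab)
#' with header columns `nom_voie`, `code_postal`, `nom_commune`. City
#' names are indexed both in their hyphenated and space-separated variants
#' (`"SAINT-MALO"` and `"SAINT MALO"`), since clinical text uses both.
#'
#' @param path Path to the address file.
#' @param stop_set,min_len Passed to [gazetteer()].
#' @return Named list of three `gazetteer` objects: `STR`, `ZIP`, `VILLE`.
#' @export
load_ban <- function(path, stop_set = default_stop_set(), min_len = 2L) {
  df <- read_delim_file(path, c("nom_voie", "code_postal", "nom_commune"))
  cities <- unique(normalize_term(df$nom_commune))
  cities <- unique(c(cities,
                     gsub("-", " ", cities, fixed = TRUE),
                     gsub(" ", "-", cities, fixed = TRUE)))
  list(
    STR = gazetteer("STR", df$nom_voie, stop_set, min_len),
    ZIP = gazetteer("ZIP", as.character(df$code_postal), stop_set, min_len),
    VILLE = gazetteer("VILLE", cities, stop_set, min_len)
  )
}

#' Load a practitioner-name gazetteer from a Health-Directory-schema file
#'
#' Expects a delimited file with header columns `Nom d'exercice` (surname)
#' and `Prenom d'exercice` (given name). Names are normalized,
#' compound-expanded (see [expand_compound()]) and ambiguity-filtered.
#'
#' @param path Path to the directory file.
#' @param stop_set,min_len Passed to [gazetteer()].
#' @return A `gazetteer` for the `DOCTOR` category.
#' @export
load_health_directory <- function(path, stop_set = default_stop_set(),
                                  min_len = 2L) {
  df <- read_delim_file(path, c("Nom d'exercice", "Prenom d'exercice"))
  names_all <- normalize_term(c(df[["Nom d'exercice"]],
                                df[["Prenom d'exercice"]]))
  # multiword cells ("LE GALL") contribute their word parts: matching is
  # per-token for person names
  words <- unlist(strsplit(names_all, " ", fixed = TRUE))
  gazetteer("DOCTOR", expand_compound(words), stop_set, min_len)
}

#' Street and title abbreviation table
#'
#' Bundled abbreviation dictionary: street-name abbreviations map to their
#' expansions and are treated as street cues; practitioner-title
#' abbreviations are role markers (contextual triggers for the DOCTOR
#' detector), not textual expansions. Keys are matched case-insensitively.
#'
#' @return Data frame with columns `abbrev`, `value`, `role` (`"expansion"`
#'   or `"role-marker"`).
#' @export
abbreviation_table <- function() {
  data.frame(
    abbrev = c("Ave", "Av", "St", "Ste", "Bd", "Bld", "Fbg", "Imp", "Pl",
               "Rte", "Sq", "Dr", "Pr", "Prof"),
    value = c("Avenue", "Avenue", "Saint", "Sainte", "Boulevard",
              "Boulevard", "Faubourg", "Impasse", "Place", "Route",
              "Square", "DOCTOR", "PROFESSOR", "PROFESSOR"),
    role = c(rep("expansion", 11L), rep("role-marker", 3L)),
    stringsAsFactors = FALSE
  )
}
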