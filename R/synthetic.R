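# Seeded generator of French-style synthetic clinical documents with gold
# PII annotations and companion gazetteer files, so the whole pipeline can
# be exercised without access to any real directory or hospital data. All
# names, streets and cities come from small bundled lists; nothing is
# sampled from real registries.

GIVEN_NAMES <- c(
  "JEAN", "PIERRE", "MARIE", "JEANNE", "PAUL", "LUC", "ANNE", "CLAIRE",
  "HUGO", "LEA", "NICOLAS", "CAMILLE", "JULIEN", "SOPHIE", "MATHIS",
  "CHLOE", "LOUIS", "EMMA", "THOMAS", "JULIE", "ALAIN", "BRIGITTE",
  "OLIVIER", "NADIA", "PASCAL", "CELINE", "DAVID", "LAURE", "ERIC",
  "AMELIE"
)
COMPOUND_GIVEN <- c("JEAN-PIERRE", "MARIE-CLAIRE", "ANNE-SOPHIE",
                    "JEAN-LUC", "PAUL-HENRI", "MARIE-HELENE")
# doctor and patient surname pools are disjoint so that a patient echo can
# never be a practitioner-gazetteer hit
SURNAMES_DOCTOR <- c(
  "DUPONT", "DURAND", "MOREAU", "LAURENT", "GARCIA", "LEFEVRE", "ROUX",
  "FOURNIER", "GIRARD", "LAMBERT", "MERCIER", "BONNET", "FRANCOIS",
  "MARTINEZ", "LEGRAND", "GARNIER", "FAURE", "ROUSSEAU", "BLANC", "HENRY"
)
SURNAMES_PATIENT <- c(
  "MARTIN", "BERNARD", "PETIT", "ROBERT", "RICHARD", "DUBOIS", "SIMON",
  "MICHEL", "LEROY", "DAVID", "BERTRAND", "MOREL", "ANDRE", "GAUTHIER",
  "CHEVALIER", "DENIS", "PERRIN", "CLEMENT", "MORIN", "NICOLAS"
)
CITY_NAMES <- c(
  "RENNES", "PARIS", "NANTES", "BREST", "VANNES", "LORIENT", "TOULOUSE",
  "LYON", "MARSEILLE", "BORDEAUX", "SAINT-MALO", "DINAN", "REDON",
  "FOUGERES", "LAVAL", "QUIMPER", "AURAY", "PONTIVY"
)
STREET_BASES <- c(
  "LA PAIX", "LA GARE", "LA LIBERATION", "LA REPUBLIQUE", "BRETAGNE",
  "LA MAIRIE", "LA FORET", "LA PLAGE", "LA COLLINE", "LA VALLEE"
)
STREET_CUES_GEN <- c("RUE", "AVENUE", "BOULEVARD", "ALLEE", "PLACE",
                     "IMPASSE")
FILLER_SENTENCES <- c(
  "Examen clinique sans particularite notable.",
  "Le patient va bien et poursuit son traitement habituel.",
  "Les constantes sont stables depuis la derniere visite.",
  "Pas de signe fonctionnel urinaire ni digestif.",
  "Une surveillance biologique reguliere est recommandee."
)

# Per-class mention counts of a large automatically annotated training
# corpus, used as the default per-category frequency profile of the
# generator (shares: DATE 27.2%, DOCTOR 21.4%, VILLE 14.0%, PHONE 12.2%,
# PATIENT 10.2%, ZIP 7.2%, STR 6.4%, EMAIL 1.5%).
TRAINING_PROFILE_COUNTS <- c(
  DOCTOR = 3883360, PATIENT = 1853646, DATE = 4948519, VILLE = 2544287,
  ZIP = 1305402, STR = 1165009, EMAIL = 276208, PHONE = 2210577
)

#' Configuration of the synthetic corpus generator
#'
#' @param n_patients Number of patients.
#' @param docs_per_patient Documents generated per patient.
#' @param mentions_per_doc Expected PII mentions per document; categories
#'   are drawn independently from `profile`.
#' @param profile Named non-negative weights over [pii_categories()];
#'   defaults to the per-class frequency profile of a large automatically
#'   annotated clinical training corpus.
#' @param typo_rate,accent_drop_rate,abbreviation_rate Per-word noise
#'   rates in `[0, 1]` applied after gold recording (distant-supervision
#'   labels are noisy; the gold surface itself may be corrupted).
#' @param gazetteer_coverage Probability that a pool entry (practitioner
#'   name, street, postal code, city) appears in the emitted gazetteer
#'   files.
#' @param n_doctor_pool,n_street_pool,n_zip_pool Sizes of the sampled
#'   name/address pools.
#' @param seed Integer seed; the generator is fully deterministic given
#'   the seed.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_patients = 20L, docs_per_patient = 2L,
                             mentions_per_doc = 12L,
                             profile = TRAINING_PROFILE_COUNTS,
                             typo_rate = 0, accent_drop_rate = 0,
                             abbreviation_rate = 0,
                             gazetteer_coverage = 1,
                             n_doctor_pool = 60L, n_street_pool = 40L,
                             n_zip_pool = 30L, seed = 42L) {
  rates <- c(typo_rate, accent_drop_rate, abbreviation_rate,
             gazetteer_coverage)
  if (any(rates < 0) || any(rates > 1)) {
    stop("rates and coverage must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(setequal(names(profile), pii_categories()))
  structure(
    list(n_patients = as.integer(n_patients),
         docs_per_patient = as.integer(docs_per_patient),
         mentions_per_doc = as.integer(mentions_per_doc),
         profile = profile[pii_categories()] / sum(profile),
         typo_rate = typo_rate, accent_drop_rate = accent_drop_rate,
         abbreviation_rate = abbreviation_rate,
         gazetteer_coverage = gazetteer_coverage,
         n_doctor_pool = as.integer(n_doctor_pool),
         n_street_pool = as.integer(n_street_pool),
         n_zip_pool = as.integer(n_zip_pool),
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

# Deterministic pools of identities and addresses shared by the corpus and
# the gazetteer files. Pools use their own RNG stream (seed + 1).
gen_pools <- function(cfg) {
  local_seed(cfg$seed + 1L, {
    givens <- c(GIVEN_NAMES, COMPOUND_GIVEN)
    doc_grid <- expand.grid(given = givens, surname = SURNAMES_DOCTOR,
                            stringsAsFactors = FALSE)
    doctors <- doc_grid[sample.int(nrow(doc_grid),
                                   min(cfg$n_doctor_pool, nrow(doc_grid))), ]
    rownames(doctors) <- NULL
    street_grid <- expand.grid(cue = STREET_CUES_GEN, base = STREET_BASES,
                               stringsAsFactors = FALSE)
    streets <- street_grid[sample.int(nrow(street_grid),
                                      min(cfg$n_street_pool,
                                          nrow(street_grid))), ]
    streets$name <- paste(streets$cue, "DE", streets$base)
    rownames(streets) <- NULL
    zips <- sprintf("%02d%03d", sample(10:95, cfg$n_zip_pool, replace = TRUE),
                    sample(0:999, cfg$n_zip_pool, replace = TRUE))
    zips <- unique(zips)
    list(doctors = doctors, streets = streets, zips = zips,
         cities = CITY_NAMES)
  })
}

#' Corrupt text with typographic noise
#'
#' Per-word independent corruption at the configured rates: a typo
#' (adjacent-character swap or single-character deletion), accent
#' removal, and abbreviation substitution of street-cue words (e.g.
#' `Avenue` to `Ave`). Deterministic given the seed.
#'
#' @param text Character scalar.
#' @param noise Named list with `typo_rate`, `accent_drop_rate`,
#'   `abbreviation_rate` (missing entries default to 0).
#' @param seed Integer seed.
#' @return Corrupted text.
#' @export
corrupt <- function(text, noise = list(), seed = 1L) {
  rates <- list(typo_rate = 0, accent_drop_rate = 0, abbreviation_rate = 0)
  rates[names(noise)] <- noise
  if (all(unlist(rates) == 0)) return(text)
  abbr <- abbreviation_table()
  abbr <- abbr[abbr$role == "expansion", ]
  local_seed(seed, {
    words <- strsplit(text, " ", fixed = TRUE)[[1]]
    for (i in seq_along(words)) {
      w <- words[i]
      if (rates$abbreviation_rate > 0 &&
          stats::runif(1) < rates$abbreviation_rate) {
        hit <- match(normalize_term(w), normalize_term(abbr$value))
        if (!is.na(hit)) w <- abbr$abbrev[hit]
      }
      if (rates$accent_drop_rate > 0 &&
          stats::runif(1) < rates$accent_drop_rate) {
        w <- stringi::stri_trans_general(w, "Latin-ASCII")
      }
      if (rates$typo_rate > 0 && nchar(w) >= 2L &&
          stats::runif(1) < rates$typo_rate) {
        ch <- strsplit(w, "", fixed = TRUE)[[1]]
        pos <- sample.int(length(ch) - 1L, 1L)
        if (stats::runif(1) < 0.5) {
          ch[c(pos, pos + 1L)] <- ch[c(pos + 1L, pos)]  # adjacent swap
        } else {
          ch <- ch[-pos]  # deletion
        }
        w <- paste(ch, collapse = "")
      }
      words[i] <- w
    }
    paste(words, collapse = " ")
  })
}

title_case <- function(x) {
  paste0(toupper(substring(x, 1L, 1L)),
         tolower(substring(x, 2L)))
}

# Build one sentence line: a list of pieces, each either plain text or a
# gold PII piece. Returns text plus a gold mention frame (sentence-local
# char offsets, token range computed by tokenizing the final line).
assemble_line <- function(pieces, categories) {
  text <- paste(vapply(pieces, `[[`, "", "text"), collapse = "")
  offs <- cumsum(c(0L, nchar(vapply(pieces, `[[`, "", "text"))))
  gold <- list()
  toks <- tokenize(text)
  for (k in seq_along(pieces)) {
    p <- pieces[[k]]
    if (is.null(p$category)) next
    cs <- offs[k]
    ce <- offs[k] + nchar(p$text)
    covered <- which(toks$start >= cs & toks$end <= ce)
    if (!length(covered)) next
    gold[[length(gold) + 1L]] <- entity_mentions(
      category = p$category, token_first = covered[1L] - 1L,
      token_last = covered[length(covered)] - 1L,
      char_start = toks$start[covered[1L]],
      char_end = toks$end[covered[length(covered)]],
      source = "manual", rule_id = "gold"
    )
  }
  list(text = text, gold = do.call(rbind, c(list(entity_mentions()), gold)))
}

piece <- function(text, category = NULL) list(text = text, category = category)

noisy <- function(x, cfg) {
  corrupt(x, list(typo_rate = cfg$typo_rate,
                  accent_drop_rate = cfg$accent_drop_rate,
                  abbreviation_rate = cfg$abbreviation_rate),
          seed = sample.int(.Machine$integer.max, 1L))
}

# One sentence line for a sampled category. Gold surfaces are corrupted
# before offsets are recorded, so the recorded spans always address the
# (possibly noisy) surface actually present in the document.
gen_line <- function(category, cfg, pools, patient) {
  pick <- function(x) x[sample.int(length(x), 1L)]
  switch(
    category,
    DATE = {
      if (stats::runif(1) < 0.25) {
        d <- sample(1:28, 1L)
        mo <- sample(1:12, 1L)
        y <- sample(1995:2023, 1L)
        surf <- paste(d, tolower(FRENCH_MONTHS[mo]), y)
        assemble_line(list(piece("Consultation de suivi le "),
                           piece(surf, "DATE"), piece(".")), "DATE")
      } else if (stats::runif(1) < 0.2) {
        assemble_line(list(piece("Patient ne le "),
                           piece(format(patient$birthdate, "%d/%m/%Y"),
                                 "DATE"),
                           piece(".")), "DATE")
      } else {
        fmt <- pick(c("%d/%m/%Y", "%d-%m-%Y", "%d.%m.%Y"))
        dt <- as.Date("1998-01-01") + sample(0:9000, 1L)
        assemble_line(list(piece("Hospitalisation du "),
                           piece(format(dt, fmt), "DATE"), piece(".")),
                      "DATE")
      }
    },
    DOCTOR = {
      i <- sample.int(nrow(pools$doctors), 1L)
      full <- paste(noisy(pools$doctors$given[i], cfg),
                    noisy(pools$doctors$surname[i], cfg))
      if (stats::runif(1) < 0.7) {
        ttl <- pick(c("Docteur", "Dr", "Pr", "Professeur"))
        assemble_line(list(piece(paste0("Vu par le ", ttl, " ")),
                           piece(full, "DOCTOR"), piece(".")), "DOCTOR")
      } else {
        assemble_line(list(piece("Courrier dicte par "),
                           piece(full, "DOCTOR"), piece(".")), "DOCTOR")
      }
    },
    PATIENT = {
      full <- paste(noisy(title_case(patient$first_name), cfg),
                    noisy(patient$last_name, cfg))
      civ <- pick(c("Monsieur", "Madame"))
      assemble_line(list(piece(paste0(civ, " ")),
                         piece(full, "PATIENT"),
                         piece(" a ete recu en consultation.")), "PATIENT")
    },
    PHONE = {
      digits <- c("02", sprintf("%02d", sample(0:99, 4L, replace = TRUE)))
      surf <- if (stats::runif(1) < 0.3) paste(digits, collapse = ".")
              else paste(digits, collapse = " ")
      assemble_line(list(piece("Secretariat joignable au "),
                         piece(surf, "PHONE"), piece(".")), "PHONE")
    },
    EMAIL = {
      i <- sample.int(nrow(pools$doctors), 1L)
      surf <- paste0(tolower(substr(pools$doctors$given[i], 1L, 1L)), ".",
                     tolower(gsub("-", "", pools$doctors$surname[i])),
                     "@chu-", tolower(gsub("-", "", pick(pools$cities))),
                     ".fr")
      assemble_line(list(piece("Contact : "), piece(surf, "EMAIL")), "EMAIL")
    },
    STR = {
      i <- sample.int(nrow(pools$streets), 1L)
      num <- sample(1:180, 1L)
      surf <- paste(num, noisy(pools$streets$name[i], cfg))
      assemble_line(list(piece("Domicilie "), piece(surf, "STR"),
                         piece(".")), "STR")
    },
    ZIP = {
      assemble_line(list(piece("Secteur postal "),
                         piece(pick(pools$zips), "ZIP"), piece(".")), "ZIP")
    },
    VILLE = {
      surf <- noisy(pick(pools$cities), cfg)
      assemble_line(list(piece("Suivi assure au CHU de "),
                         piece(surf, "VILLE"), piece(".")), "VILLE")
    },
    stop("unknown category: ", category, call. = FALSE)
  )
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Generate a synthetic gold-annotated corpus
#'
#' Each document is an HTML page of one-sentence paragraphs: a plain
#' header, PII-bearing lines sampled from the configured category
#' profile (dates, practitioner signatures, patient echoes, address,
#' phone and email lines) and neutral clinical filler. Gold mentions are
#' recorded at generation time with sentence-local offsets that remain
#' valid after HTML extraction; noise is applied to the surfaces before
#' the offsets are recorded, so gold spans address the corrupted text.
#'
#' @param cfg A [synthetic_config()].
#' @return List of gold documents, each a list with `doc` (a
#'   [source_document()]), `sent_texts` (character vector, one per
#'   sentence) and `gold` (list of mention frames, one per sentence).
#' @export
gen_corpus <- function(cfg = synthetic_config()) {
  pools <- gen_pools(cfg)
  local_seed(cfg$seed, {
    out <- list()
    for (p in seq_len(cfg$n_patients)) {
      patient <- list(
        id = sprintf("PAT%05d", p),
        first_name = sample(c(GIVEN_NAMES, COMPOUND_GIVEN), 1L),
        last_name = sample(SURNAMES_PATIENT, 1L),
        birthdate = as.Date("1935-01-01") + sample(0:25000, 1L)
      )
      for (d in seq_len(cfg$docs_per_patient)) {
        n_m <- max(1L, stats::rpois(1L, cfg$mentions_per_doc))
        cats <- sample(names(cfg$profile), n_m, replace = TRUE,
                       prob = cfg$profile)
        lines <- lapply(cats, gen_line, cfg = cfg, pools = pools,
                        patient = patient)
        fill <- sample(FILLER_SENTENCES, min(2L, length(FILLER_SENTENCES)))
        lines <- append(lines,
                        lapply(fill, function(f)
                          list(text = f, gold = entity_mentions())),
                        after = sample(0:length(lines), 1L))
        header <- list(text = "COMPTE RENDU DE CONSULTATION",
                       gold = entity_mentions())
        lines <- c(list(header), lines)
        raw <- paste0(
          "<html><body>\n",
          paste0("<p>", html_escape(vapply(lines, `[[`, "", "text")),
                 "</p>\n", collapse = ""),
          "</body></html>\n"
        )
        doc <- source_document(
          doc_id = sprintf("%s-D%02d", patient$id, d),
          patient_id = patient$id,
          raw = raw,
          metadata = list(patient_first_name = patient$first_name,
                          patient_last_name = patient$last_name,
                          birthdate = patient$birthdate),
          dialect = "native-HTML"
        )
        out[[length(out) + 1L]] <- list(
          doc = doc,
          sent_texts = vapply(lines, `[[`, "", "text"),
          gold = lapply(lines, `[[`, "gold")
        )
      }
    }
    out
  })
}

#' Emit gazetteer files for a synthetic corpus
#'
#' Writes two delimited files in the column schemas the loaders expect: a
#' national-address-style file (`nom_voie`, `code_postal`, `nom_commune`)
#' and a health-directory-style file (`Nom d'exercice`,
#' `Prenom d'exercice`). Each pool entry is included with probability
#' `gazetteer_coverage`; the files are deterministic given the seed.
#'
#' @param cfg A [synthetic_config()].
#' @param dir Output directory (created if needed).
#' @return Named list with the two file paths (`ban`, `rpps`), invisibly.
#' @export
gen_gazetteers <- function(cfg = synthetic_config(), dir = tempdir()) {
  pools <- gen_pools(cfg)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  local_seed(cfg$seed + 2L, {
    cov <- function(n) stats::runif(n) < cfg$gazetteer_coverage
    streets <- pools$streets$name[cov(nrow(pools$streets))]
    zips <- pools$zips[cov(length(pools$zips))]
    cities <- pools$cities[cov(length(pools$cities))]
    k <- max(length(streets), length(zips), length(cities), 1L)
    ban <- data.frame(
      nom_voie = if (length(streets)) rep_len(streets, k) else rep("", k),
      code_postal = if (length(zips)) rep_len(zips, k) else rep("", k),
      nom_commune = if (length(cities)) rep_len(cities, k) else rep("", k),
      stringsAsFactors = FALSE
    )
    keep_doc <- cov(nrow(pools$doctors))
    rpps <- data.frame(
      `Nom d'exercice` = pools$doctors$surname[keep_doc],
      `Prenom d'exercice` = pools$doctors$given[keep_doc],
      check.names = FALSE, stringsAsFactors = FALSE
    )
    ban_path <- file.path(dir, "ban_synthetic.csv")
    rpps_path <- file.path(dir, "health_directory_synthetic.csv")
    utils::write.table(ban, ban_path, sep = ";", row.names = FALSE,
                       quote = TRUE, fileEncoding = "UTF-8")
    utils::write.table(rpps, rpps_path, sep = ";", row.names = FALSE,
                       quote = TRUE, fileEncoding = "UTF-8")
    invisible(list(ban = ban_path, rpps = rpps_path))
  })
}

# Surrogate sampler for mask_document(): a same-category plausible value,
# guaranteed to differ from the masked surface.
surrogate_value <- function(category, surface, seed) {
  local_seed(seed, {
    pick <- function(x) x[sample.int(length(x), 1L)]
    val <- switch(
      category,
      PATIENT = ,
      DOCTOR = paste(pick(GIVEN_NAMES),
                     pick(c(SURNAMES_DOCTOR, SURNAMES_PATIENT))),
      DATE = format(as.Date("1990-01-01") + sample(0:12000, 1L), "%d/%m/%Y"),
      EMAIL = paste0("contact", sample(10:99, 1L), "@example.fr"),
      PHONE = paste(sprintf("%02d", c(2L, sample(0:99, 4L, TRUE))),
                    collapse = " "),
      STR = paste(sample(1:150, 1L), pick(STREET_CUES_GEN), "DE",
                  pick(STREET_BASES)),
      ZIP = sprintf("%05d", sample(10000:95999, 1L)),
      VILLE = pick(CITY_NAMES),
      stop("unknown category: ", category, call. = FALSE)
    )
    while (val == surface) val <- paste0(val, "X")
    val
  })
}
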