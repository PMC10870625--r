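surfaces_of <- function(sent, m) {
  vapply(seq_len(nrow(m)),
         function(k) span_surface(sent, m[k, , drop = FALSE]), character(1))
}

test_that("numeric dates validate day/month bounds", {
  hits <- detect_dates(sentence("rendez-vous le 02/07/1985"))
  expect_equal(nrow(hits), 1L)
  expect_identical(hits$category, "DATE")
  # enumerate invalid day/month pairs: none may fire
  set.seed(21)
  bad_days <- sprintf("%02d/%02d/2020", sample(32:99, 8), sample(1:12, 8, TRUE))
  bad_months <- sprintf("%02d/%02d/2020", sample(1:28, 8, TRUE), sample(13:99, 8))
  for (x in c(bad_days, bad_months, "45/99/2020")) {
    expect_equal(nrow(detect_dates(sentence(x))), 0L, info = x)
  }
  # all valid pairs fire
  good <- sprintf("%02d/%02d/20", sample(1:31, 8, TRUE), sample(1:12, 8, TRUE))
  for (x in good) {
    expect_equal(nrow(detect_dates(sentence(x))), 1L, info = x)
  }
})

test_that("date formats: separators, two-digit years, ISO and lexical", {
  s <- sentence("vu 03-01-2020 puis 3.1.20 puis 2020-01-03")
  expect_equal(nrow(detect_dates(s)), 3L)
  lex <- sentence("opere le mardi 3 janvier 2020 au matin")
  m <- detect_dates(lex)
  expect_equal(nrow(m), 1L)
  expect_identical(surfaces_of(lex, m), "mardi 3 janvier 2020")
  abbr <- sentence("revu le 12 sept 2019")
  expect_equal(nrow(detect_dates(abbr)), 1L)
})

test_that("phone detection covers spaced pairs, dotted tokens, 10-digit runs", {
  s1 <- sentence("appel au 02 99 28 43 21 ce jour")
  m1 <- detect_phone(s1)
  expect_identical(surfaces_of(s1, m1), "02 99 28 43 21")
  expect_equal(nrow(detect_phone(sentence("fax 00.00.00"))), 1L)
  expect_equal(nrow(detect_phone(sentence("ligne 0299284321"))), 1L)
  expect_equal(nrow(detect_phone(sentence("en 2020"))), 0L)
  # two pairs are below the floor; seven exceed the ceiling
  expect_equal(nrow(detect_phone(sentence("12 34"))), 0L)
  expect_equal(nrow(detect_phone(sentence("12 34 56 78 90 12 34"))), 0L)
})

test_that("zip requires gazetteer membership or a nearby city/street cue", {
  gz <- gazetteer("ZIP", "35000")
  gv <- gazetteer("VILLE", "Rennes")
  s <- sentence("35000 RENNES")
  expect_equal(nrow(detect_zip(s, gaz_zip = gz)), 1L)
  # not in gazetteer, but supported by adjacent city
  s2 <- sentence("99999 RENNES")
  expect_equal(nrow(detect_zip(s2, gaz_zip = gz, gaz_ville = gv)), 1L)
  # bare five digits with no support
  expect_equal(nrow(detect_zip(sentence("99999"), gaz_zip = gz)), 0L)
  # six digits never
  expect_equal(nrow(detect_zip(sentence("123456 RENNES"), gaz_zip = gz,
                               gaz_ville = gv)), 0L)
})

test_that("email matches a reference address grammar", {
  ok <- c("j.dupont@chu-rennes.fr", "a@b.fr", "p-h.le_gall@x.y.org")
  bad <- c("arobase", "@rennes.fr", "jean@", "jean@chu", "jean dupont")
  ref <- function(x) grepl("^[^@\\s]+@[^@\\s]+\\.[a-z]{2,}$", x, perl = TRUE)
  for (x in c(ok, bad)) {
    got <- nrow(detect_email(sentence(paste("mail", x)))) > 0
    expect_equal(got, ref(x), info = x)
  }
})

test_that("street mentions anchor on cues and extend over capitalized runs", {
  s <- sentence("habite 12 RUE DE LA PAIX depuis peu")
  m <- detect_street(s)
  expect_identical(surfaces_of(s, m), "12 RUE DE LA PAIX")
  # lowercase prose cue without continuation
  expect_equal(nrow(detect_street(sentence("il continue sa rue"))), 0L)
  # abbreviation expansion acts as cue
  s3 <- sentence("au 3 Ave de Bretagne")
  m3 <- detect_street(s3)
  expect_identical(surfaces_of(s3, m3), "3 Ave de Bretagne")
  # gazetteer continuation rescues lowercase addresses
  gs <- gazetteer("STR", "rue de la paix")
  s4 <- sentence("domicile rue de la paix")
  expect_equal(nrow(detect_street(s4, gaz_str = gs)), 1L)
})

test_that("city matching is longest-first with contextual lowercase support", {
  gv <- gazetteer("VILLE", c("Rennes", "Paris", "Saint-Malo"))
  s <- sentence("transfert vers RENNES ce jour")
  expect_equal(nrow(detect_city(s, gaz_ville = gv)), 1L)
  # lowercase requires a zip or street cue nearby
  expect_equal(nrow(detect_city(sentence("il habite rennes"),
                                gaz_ville = gv)), 0L)
  s2 <- sentence("35000 rennes")
  expect_equal(nrow(detect_city(s2, gaz_ville = gv)), 1L)
  # longest match only covers the dictionary span
  s3 <- sentence("lu dans PARIS MATCH hier")
  m3 <- detect_city(s3, gaz_ville = gv)
  expect_identical(surfaces_of(s3, m3), "PARIS")
  # multiword hyphenated city is one hit
  s4 <- sentence("adresse a SAINT-MALO")
  expect_identical(surfaces_of(s4, detect_city(s4, gaz_ville = gv)),
                   "SAINT-MALO")
})

test_that("doctor detection: role triggers and gazetteer hits", {
  s <- sentence("Monsieur le Docteur JEAN DUPONT")
  m <- detect_doctor(s)
  expect_identical(surfaces_of(s, m), "JEAN DUPONT")
  # title excluded from the span
  expect_equal(m$token_first, 3L)
  expect_equal(nrow(detect_doctor(sentence("le docteur est absent"))), 0L)
  gd <- gazetteer("DOCTOR", c("Durand", "Jean"))
  s2 <- sentence("DURAND a prescrit le traitement")
  expect_identical(surfaces_of(s2, detect_doctor(s2, gaz_doc = gd)), "DURAND")
  # lowercase gazetteer hits do not fire without capitalization
  expect_equal(nrow(detect_doctor(sentence("durand a prescrit"),
                                  gaz_doc = gd)), 0L)
})

test_that("patient detection matches metadata echoes and birthdates", {
  doc <- source_document("d1", "p1", "x", metadata = list(
    patient_first_name = "Paul", patient_last_name = "MARTIN",
    birthdate = as.Date("1985-07-02")))
  keys <- patient_record_keys(doc)
  s <- sentence("Monsieur Paul MARTIN est sorti")
  m <- detect_patient(s, keys)
  expect_identical(surfaces_of(s, m), "Paul MARTIN")
  expect_identical(unique(m$category), "PATIENT")
  # birthdate in a configured format becomes DATE
  s2 <- sentence("ne le 02/07/1985 a RENNES")
  m2 <- detect_patient(s2, keys)
  expect_true("DATE" %in% m2$category)
  # diacritic-insensitive
  doc2 <- source_document("d2", "p2", "x", metadata = list(
    patient_first_name = "Héloïse", patient_last_name = "LE GALL"))
  k2 <- patient_record_keys(doc2)
  s3 <- sentence("Madame Heloise GALL")
  expect_equal(nrow(detect_patient(s3, k2)), 1L)
  # no metadata, no mentions
  empty_keys <- patient_record_keys(source_document("d3", "p3", "x"))
  expect_equal(nrow(detect_patient(s, empty_keys)), 0L)
})

test_that("the cascade resolves overlaps: longest span, then priority", {
  gaz <- list(VILLE = gazetteer("VILLE", "Rennes"),
              ZIP = gazetteer("ZIP", "35000"),
              DOCTOR = gazetteer("DOCTOR", c("Jean", "Dupont")))
  s <- sentence("Dr JEAN DUPONT, 12 RUE DE LA PAIX, 35000 RENNES")
  m <- annotate_sentence(s, gazetteers = gaz)
  expect_identical(m$category, c("DOCTOR", "STR", "ZIP", "VILLE"))
  # non-overlapping and sorted
  expect_true(all(m$char_start[-1] >= m$char_end[-nrow(m)]))
  expect_equal(nrow(annotate_sentence(sentence("rien a signaler"))), 0L)
})

test_that("priority breaks exact ties: patient beats doctor on equal span", {
  doc <- source_document("d1", "p1", "x", metadata = list(
    patient_first_name = "Jean", patient_last_name = "DUPONT"))
  keys <- patient_record_keys(doc)
  gaz <- list(DOCTOR = gazetteer("DOCTOR", c("Jean", "Dupont")))
  s <- sentence("Monsieur Jean DUPONT present")
  m <- annotate_sentence(s, gazetteers = gaz, keys = keys)
  expect_identical(m$category, "PATIENT")
})

test_that("the cascade is deterministic and never yields overlaps", {
  setup <- build_eval_setup(synthetic_config(n_patients = 4L, seed = 23L))
  for (i in seq_along(setup$sentences)) {
    m1 <- annotate_sentence(setup$sentences[[i]],
                            gazetteers = setup$gazetteers)
    m2 <- annotate_sentence(setup$sentences[[i]],
                            gazetteers = setup$gazetteers)
    expect_identical(m1, m2)
    if (nrow(m1) > 1L) {
      expect_true(all(m1$char_start[-1] >= m1$char_end[-nrow(m1)]))
    }
    expect_true(all(m1$char_end <= nchar(setup$sentences[[i]]$text)))
  }
})

test_that("shrinking a gazetteer can only decrease mention counts", {
  cfg <- synthetic_config(n_patients = 4L, seed = 29L)
  setup <- build_eval_setup(cfg)
  full_gaz <- setup$gazetteers
  smaller <- full_gaz
  smaller$DOCTOR <- gazetteer(
    "DOCTOR", head(full_gaz$DOCTOR$entries, length(full_gaz$DOCTOR$entries) %/% 2))
  n_full <- sum(vapply(setup$sentences, function(s)
    nrow(detect_doctor(s, gaz_doc = full_gaz$DOCTOR)), numeric(1)))
  n_small <- sum(vapply(setup$sentences, function(s)
    nrow(detect_doctor(s, gaz_doc = smaller$DOCTOR)), numeric(1)))
  expect_lte(n_small, n_full)
})
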