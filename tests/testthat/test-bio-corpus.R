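test_that("bio_encode tags the worked example", {
  s <- sentence("Monsieur le Docteur JEAN DUPONT")
  m <- annotate_sentence(s)
  expect_identical(bio_encode(s, m),
                   c("O", "O", "O", "B-DOCTOR", "I-DOCTOR"))
  expect_identical(bio_encode(s, entity_mentions()), rep("O", 5L))
})

test_that("bio_decode repairs orphan I- tags and handles runs", {
  m <- bio_decode(c("O", "B-DATE", "I-DATE", "O"))
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$token_first, m$token_last), c(1L, 2L))
  expect_identical(m$category, "DATE")
  # orphan I at sentence start opens a mention
  r <- bio_decode(c("I-ZIP", "O"))
  expect_equal(nrow(r), 1L)
  expect_identical(r$category, "ZIP")
  expect_equal(r$token_first, 0L)
  # category switch without B starts a new mention
  sw <- bio_decode(c("B-DATE", "I-ZIP"))
  expect_equal(nrow(sw), 2L)
  # adjacent B-B of same class are two mentions
  bb <- bio_decode(c("B-VILLE", "B-VILLE"))
  expect_equal(nrow(bb), 2L)
  expect_equal(nrow(bio_decode(c("O", "O"))), 0L)
})

test_that("bio_decode . bio_encode is the identity on mention sets", {
  set.seed(31)
  for (rep in 1:1000) {
    txt <- random_sentence_text()
    s <- sentence(txt)
    m <- random_mentions(s$tokens)
    tags <- bio_encode(s, m)
    back <- bio_decode(tags, s$tokens)
    expect_equal(nrow(back), nrow(m))
    if (nrow(m)) {
      expect_identical(back$category, m$category)
      expect_identical(back$token_first, m$token_first)
      expect_identical(back$token_last, m$token_last)
      expect_identical(back$char_start, m$char_start)
      expect_identical(back$char_end, m$char_end)
    }
  }
})

test_that("filter_sentences keeps exactly the annotated sentences", {
  mk <- function(txt, ann) {
    s <- sentence(txt)
    m <- if (ann) entity_mentions("DATE", 0L, 0L, s$tokens$start[1],
                                  s$tokens$end[1], "manual", "")
         else entity_mentions()
    corpus_record(s, m)
  }
  corpus <- list(mk("un deux", TRUE), mk("trois", FALSE), mk("quatre", FALSE))
  kept <- filter_sentences(corpus)
  expect_length(kept, 1L)
  # brute-force predicate oracle on a generated corpus
  set.seed(33)
  corpus2 <- lapply(1:40, function(i) mk(random_sentence_text(),
                                         runif(1) < 0.5))
  kept2 <- filter_sentences(corpus2)
  want <- Filter(function(r) nrow(r$mentions) > 0, corpus2)
  expect_identical(kept2, want)
  # idempotent; identity on fully annotated input
  expect_identical(filter_sentences(kept2), kept2)
})

test_that("split_by_patient is deterministic, disjoint and near the ratios", {
  ids <- sprintf("P%05d", 1:10000)
  a <- split_by_patient(ids, seed = 7L)
  b <- split_by_patient(ids, seed = 7L)
  expect_identical(a, b)
  # every patient in exactly one partition
  expect_setequal(names(a), ids)
  expect_true(all(a %in% c("train", "valid", "test")))
  frac <- unname(table(a)["train"]) / length(ids)
  expect_gte(frac, 0.78)
  expect_lte(frac, 0.82)
  # documents of one patient always travel together
  docs <- rep(c("pA", "pB"), each = 5)
  sp <- split_by_patient(docs, seed = 1L)
  expect_length(sp, 2L)
  # assignment is independent of corpus composition
  sub <- split_by_patient(ids[1:100], seed = 7L)
  expect_identical(as.vector(sub), as.vector(a[1:100]))
  expect_error(split_by_patient(ids, ratios = c(0.5, 0.5, 0.5)), "sum")
})

test_that("corpus share percentages reproduce the reference distribution", {
  counts <- read.csv(system.file("extdata", "reference_corpus_counts.csv",
                                 package = "deidfr"), check.names = FALSE)
  train <- counts[counts$split == "training", pii_categories()]
  shares <- category_shares(unlist(train))
  expect_equal(unname(shares["DATE"]), 27.2)
  expect_equal(unname(shares["DOCTOR"]), 21.4)
  expect_equal(sum(shares), 100, tolerance = 0.2)
  # single-class corpus
  expect_equal(unname(category_shares(c(DATE = 5))["DATE"]), 100.0)
})

test_that("corpus_stats counts equal a brute-force tally", {
  setup <- build_eval_setup(synthetic_config(n_patients = 3L, seed = 37L))
  recs <- lapply(seq_along(setup$sentences), function(i)
    corpus_record(setup$sentences[[i]], setup$gold[[i]]))
  st <- corpus_stats(recs)
  tally <- table(factor(unlist(lapply(setup$gold, function(m) m$category)),
                        levels = pii_categories()))
  expect_equal(unname(st$counts), as.integer(tally))
  expect_equal(st$n_sentences, length(recs))
})

test_that("jsonl write/read round-trips byte-identically", {
  setup <- build_eval_setup(synthetic_config(n_patients = 2L, seed = 41L))
  recs <- lapply(seq_along(setup$sentences), function(i)
    corpus_record(setup$sentences[[i]], setup$pred[[i]],
                  meta = list(ID_PAT = "p", ID_ENTREPOT = "d", CODE = "C")))
  path <- tempfile(fileext = ".jsonl")
  write_jsonl(recs, path)
  back <- read_jsonl(path)
  path2 <- tempfile(fileext = ".jsonl")
  write_jsonl(back, path2)
  expect_identical(readLines(path2), readLines(path))
  # mentions survive with spans and token ranges intact
  expect_equal(length(back), length(recs))
  for (i in seq_along(recs)) {
    expect_identical(back[[i]]$sent$text, recs[[i]]$sent$text)
    expect_equal(back[[i]]$mentions$category, recs[[i]]$mentions$category)
    expect_equal(back[[i]]$mentions$char_start, recs[[i]]$mentions$char_start)
    expect_equal(back[[i]]$mentions$token_first, recs[[i]]$mentions$token_first)
  }
  # empty corpus
  p3 <- tempfile(); write_jsonl(list(), p3)
  expect_length(read_jsonl(p3), 0L)
  # malformed line reports its number
  p4 <- tempfile()
  writeLines(c(as.character(readLines(path)[1]), "{broken"), p4)
  expect_error(read_jsonl(p4), "line 2")
})

test_that("conll files round-trip token/tag sequences", {
  s1 <- sentence("Dr DUPONT consulte")
  s2 <- sentence("RAS ce jour")
  recs <- list(corpus_record(s1, annotate_sentence(s1)),
               corpus_record(s2, entity_mentions()))
  path <- tempfile(fileext = ".conll")
  write_conll(recs, path)
  back <- read_conll(path)
  expect_length(back, 2L)
  expect_identical(back[[1]]$token, s1$tokens$text)
  expect_identical(back[[1]]$tag, bio_encode(s1, recs[[1]]$mentions))
  expect_identical(back[[2]]$tag, rep("O", 3L))
})
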