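# Shared fixtures, all built in code.

# Generate a synthetic corpus plus loaded gazetteers and, per sentence,
# the gold and cascade-predicted mention sets.
build_eval_setup <- function(cfg) {
  corp <- gen_corpus(cfg)
  dir <- file.path(tempfile("gaz"), "g")
  paths <- gen_gazetteers(cfg, dir)
  gaz <- c(load_ban(paths$ban),
           list(DOCTOR = load_health_directory(paths$rpps)))
  gold <- list()
  pred <- list()
  sentences <- list()
  for (gd in corp) {
    parsed <- parse_document(gd$doc)
    keys <- patient_record_keys(gd$doc)
    for (i in seq_along(parsed$sentences)) {
      gold[[length(gold) + 1L]] <- gd$gold[[i]]
      pred[[length(pred) + 1L]] <-
        annotate_sentence(parsed$sentences[[i]], gazetteers = gaz,
                          keys = keys)
      sentences[[length(sentences) + 1L]] <- parsed$sentences[[i]]
    }
  }
  list(corpus = corp, gazetteers = gaz, gold = gold, pred = pred,
       sentences = sentences)
}

# Random non-overlapping mention set over n_tokens tokens.
random_mentions <- function(tokens, max_mentions = 3L) {
  n <- nrow(tokens)
  if (n == 0L) return(entity_mentions())
  k <- sample(0:max_mentions, 1L)
  taken <- rep(FALSE, n)
  out <- list()
  for (i in seq_len(k)) {
    a <- sample.int(n, 1L)
    b <- min(n, a + sample(0:2, 1L))
    if (any(taken[a:b])) next
    taken[a:b] <- TRUE
    out[[length(out) + 1L]] <- entity_mentions(
      category = sample(pii_categories(), 1L),
      token_first = a - 1L, token_last = b - 1L,
      char_start = tokens$start[a], char_end = tokens$end[b],
      source = "manual", rule_id = "rand"
    )
  }
  m <- do.call(rbind, c(list(entity_mentions()), out))
  m <- m[order(m$char_start), , drop = FALSE]
  rownames(m) <- NULL
  m
}

random_sentence_text <- function(n_words = NULL) {
  words <- c("le", "patient", "examen", "suivi", "clinique", "traitement",
             "RENNES", "DUPONT", "12/03/2020", "35000", "bien", "stable")
  if (is.null(n_words)) n_words <- sample(3:10, 1L)
  paste(sample(words, n_words, replace = TRUE), collapse = " ")
}
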