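# Direct-formula oracle, written independently of the package internals.
oracle_fleiss <- function(m) {
  n <- sum(m[1, ]); N <- nrow(m)
  PA <- sum(m * (m - 1)) / (N * n * (n - 1))
  pj <- colSums(m) / sum(m)
  PE <- sum(pj^2)
  (PA - PE) / (1 - PE)
}

test_that("fleiss_kappa hits the closed-form anchor cases", {
  # unanimity
  m <- rbind(c(4, 0), c(0, 4), c(4, 0), c(0, 4))
  expect_equal(fleiss_kappa(m), 1)
  # two raters, total disagreement, balanced marginals
  m2 <- matrix(1, nrow = 10, ncol = 2)
  expect_equal(fleiss_kappa(m2), -1)
  # single-category degenerate input is defined as 1 and flagged
  m3 <- matrix(3, nrow = 5, ncol = 1)
  k3 <- fleiss_kappa(m3)
  expect_equal(as.numeric(k3), 1)
  expect_true(isTRUE(attr(k3, "degenerate")))
  expect_error(fleiss_kappa(rbind(c(1, 0), c(1, 1))), "same number")
})

test_that("fleiss_kappa equals the direct formula on random matrices", {
  set.seed(59)
  for (rep_i in 1:100) {
    n_raters <- sample(2:5, 1)
    n_items <- sample(4:12, 1)
    n_cats <- sample(2:4, 1)
    m <- t(vapply(seq_len(n_items), function(i) {
      as.integer(rmultinom(1, n_raters, rep(1, n_cats)))
    }, integer(n_cats)))
    if (sum(colSums(m) > 0) < 2) next  # degenerate, handled above
    expect_equal(as.numeric(fleiss_kappa(m)), oracle_fleiss(m))
  }
})

test_that("kappa is invariant under category relabeling", {
  set.seed(61)
  m <- t(rmultinom(20, 3, c(0.5, 0.3, 0.2)))
  expect_equal(as.numeric(fleiss_kappa(m)),
               as.numeric(fleiss_kappa(m[, c(3, 1, 2)])))
})

make_ratings <- function(n_docs, tokens_per_doc, raters, flip = 0,
                         labels = c("O", "DATE", "VILLE")) {
  out <- list()
  for (d in seq_len(n_docs)) {
    truth <- sample(labels, tokens_per_doc, replace = TRUE)
    for (r in raters) {
      lab <- truth
      swap <- runif(tokens_per_doc) < flip
      lab[swap] <- sample(labels, sum(swap), replace = TRUE)
      out[[length(out) + 1L]] <- data.frame(
        doc = paste0("doc", d), item = seq_len(tokens_per_doc),
        rater = r, label = lab, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

test_that("per_tag_kappa equals the binary-reduction oracle", {
  set.seed(67)
  ratings <- make_ratings(4, 30, c("a1", "a2", "a3"), flip = 0.2)
  for (tag in c("O", "DATE", "VILLE")) {
    bin <- ratings
    bin$label <- ifelse(bin$label == tag, "X", "Y")
    expect_equal(as.numeric(per_tag_kappa(ratings, tag)),
                 as.numeric(fleiss_kappa(rating_matrix(bin))), info = tag)
  }
})

test_that("pairwise agreement is symmetric with unit diagonal and NA gaps", {
  set.seed(71)
  r12 <- make_ratings(3, 20, c("a1", "a2"), flip = 0.1)
  r3 <- make_ratings(2, 20, "a3")
  r3$doc <- paste0("other", r3$doc)  # a3 shares no document
  res <- pairwise_agreement(rbind(r12, r3))
  expect_identical(res$kappa, t(res$kappa))
  expect_equal(unname(diag(res$kappa)), rep(1, 3))
  expect_true(is.na(res$kappa["a1", "a3"]))
  # identical annotations agree perfectly
  same <- make_ratings(2, 15, "a1")
  twin <- same; twin$rater <- "a2"
  expect_equal(unname(pairwise_agreement(rbind(same, twin))$kappa["a1", "a2"]),
               1)
  # two-rater value equals the n = 2 Fleiss reduction
  expect_equal(unname(res$kappa["a1", "a2"]),
               as.numeric(fleiss_kappa(rating_matrix(r12, 2L))))
})

test_that("bootstrap interval brackets the estimate; perfect agreement
           collapses to (1,1); fixed seed reproduces", {
  set.seed(73)
  ratings <- make_ratings(8, 25, c("a1", "a2"), flip = 0.15)
  k <- as.numeric(fleiss_kappa(rating_matrix(ratings)))
  ci <- kappa_ci(ratings, reps = 200, seed = 5)
  expect_lte(ci[1], k)
  expect_gte(ci[2], k)
  expect_identical(ci, kappa_ci(ratings, reps = 200, seed = 5))
  perfect <- make_ratings(4, 20, "a1")
  twin <- perfect; twin$rater <- "a2"
  expect_equal(kappa_ci(rbind(perfect, twin), reps = 100, seed = 1),
               c(1, 1))
  expect_error(kappa_ci(ratings, reps = 10), "at least 100")
})

test_that("kappa decreases as independent corruption increases", {
  set.seed(79)
  kappas <- vapply(c(0, 0.15, 0.4, 0.8), function(eps) {
    as.numeric(fleiss_kappa(rating_matrix(
      make_ratings(6, 60, c("a1", "a2", "a3"), flip = eps))))
  }, numeric(1))
  expect_true(all(diff(kappas) < 0))
})

test_that("ratings_from_corpora labels tokens with covering mentions", {
  s <- sentence("Dr DUPONT consulte")
  m <- annotate_sentence(s)
  r1 <- list(corpus_record(s, m, meta = list(ID_PAT = "p")))
  r2 <- list(corpus_record(s, entity_mentions(), meta = list(ID_PAT = "p")))
  ratings <- ratings_from_corpora(list(a1 = r1, a2 = r2),
                                  doc_ids = "doc1")
  expect_equal(nrow(ratings), 6L)  # 3 tokens x 2 raters
  expect_setequal(ratings$label[ratings$rater == "a1"],
                  c("O", "DOCTOR"))
  expect_true(all(ratings$label[ratings$rater == "a2"] == "O"))
})
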