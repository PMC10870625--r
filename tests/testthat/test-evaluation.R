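ref_table <- function(which) {
  read.csv(system.file("extdata", paste0("reference_scores_", which, ".csv"),
                       package = "deidfr"), stringsAsFactors = FALSE)
}

test_that("strict matching counts exact span+type agreements one-to-one", {
  g <- entity_mentions(c("DATE", "VILLE", "ZIP"), c(0L, 2L, 4L),
                       c(0L, 2L, 4L), c(0L, 10L, 20L), c(5L, 15L, 25L),
                       "manual", "")
  p <- entity_mentions(c("DATE", "VILLE"), c(0L, 2L), c(0L, 2L),
                       c(0L, 11L), c(5L, 15L), "pattern", "")
  counts <- match_mentions(g, p)
  rep <- prf(counts)
  micro <- rep[rep$class == "micro avg", ]
  expect_equal(micro$precision, 0.5)
  expect_equal(micro$recall, 1 / 3)
  expect_equal(micro$f1, 0.4)
  # identical sets: no errors at all
  same <- match_mentions(g, g)
  expect_equal(sum(same$fp), 0L)
  expect_equal(sum(same$fn), 0L)
  # overlapping mentions are rejected as input
  bad <- entity_mentions(c("DATE", "DATE"), c(0L, 0L), c(1L, 1L),
                         c(0L, 3L), c(5L, 8L), "manual", "")
  expect_error(match_mentions(bad, p), "overlapping")
})

test_that("strict counts match an exhaustive matching oracle", {
  # brute force: maximum one-to-one matching over all injections
  oracle_tp <- function(g, p) {
    if (nrow(p) == 0L || nrow(g) == 0L) return(0L)
    eq <- outer(seq_len(nrow(p)), seq_len(nrow(g)), Vectorize(function(i, j) {
      p$category[i] == g$category[j] &&
        p$char_start[i] == g$char_start[j] && p$char_end[i] == g$char_end[j]
    }))
    best <- 0L
    perms <- function(v) if (length(v) <= 1L) list(v) else
      do.call(c, lapply(seq_along(v), function(i)
        lapply(perms(v[-i]), function(rest) c(v[i], rest))))
    for (ord in perms(seq_len(nrow(p)))) {
      used <- rep(FALSE, nrow(g)); tp <- 0L
      for (i in ord) {
        j <- which(eq[i, ] & !used)[1]
        if (!is.na(j)) { used[j] <- TRUE; tp <- tp + 1L }
      }
      best <- max(best, tp)
    }
    best
  }
  set.seed(47)
  for (rep_i in 1:30) {
    s <- sentence(random_sentence_text(10))
    g <- random_mentions(s$tokens, 3L)
    p <- random_mentions(s$tokens, 3L)
    counts <- match_mentions(g, p)
    expect_equal(sum(counts$tp), oracle_tp(g, p))
    expect_equal(sum(counts$fp), nrow(p) - oracle_tp(g, p))
    expect_equal(sum(counts$fn), nrow(g) - oracle_tp(g, p))
  }
})

test_that("token mode gives partial credit per covered token", {
  s <- sentence("le 3 janvier 2020 ici")
  g <- entity_mentions("DATE", 1L, 3L, s$tokens$start[2], s$tokens$end[4],
                       "manual", "")
  p <- entity_mentions("DATE", 1L, 2L, s$tokens$start[2], s$tokens$end[3],
                       "pattern", "")
  strict <- match_mentions(g, p, "strict")
  expect_equal(sum(strict$tp), 0L)
  tok <- match_mentions(g, p, "token")
  expect_equal(tok$tp[tok$class == "DATE"], 2L)
  expect_equal(tok$fn[tok$class == "DATE"], 1L)
  expect_equal(tok$fp[tok$class == "DATE"], 0L)
})

test_that("token-mode scoring agrees with an independent per-token oracle", {
  setup <- build_eval_setup(synthetic_config(n_patients = 3L, seed = 53L))
  counts <- match_mentions(setup$gold, setup$pred, "token")
  # oracle: expand both sides to per-token label vectors and compare
  for (cl in pii_categories()) {
    tp <- fp <- fn <- 0L
    for (u in seq_along(setup$gold)) {
      n <- nrow(setup$sentences[[u]]$tokens)
      lab <- function(m) {
        v <- rep("O", n)
        for (k in seq_len(nrow(m)))
          v[(m$token_first[k] + 1):(m$token_last[k] + 1)] <- m$category[k]
        v
      }
      gl <- lab(setup$gold[[u]]); pl <- lab(setup$pred[[u]])
      tp <- tp + sum(gl == cl & pl == cl)
      fp <- fp + sum(pl == cl & gl != cl)
      fn <- fn + sum(gl == cl & pl != cl)
    }
    row <- counts[counts$class == cl, ]
    expect_equal(c(row$tp, row$fp, row$fn), c(tp, fp, fn), info = cl)
  }
})

test_that("prf reproduces the published aggregate identities", {
  # micro F1 is the harmonic mean of the printed micro P and R
  expect_equal(2 * 0.9756 * 0.9637 / (0.9756 + 0.9637), 0.9696,
               tolerance = 1e-4)
  tab <- ref_table("neural")
  per <- tab[!grepl("avg", tab$class), ]
  # harmonic-mean identity on the rows where printed rounding permits
  for (cl in c("VILLE", "ZIP", "EMAIL", "PATIENT")) {
    r <- per[per$class == cl, ]
    expect_equal(2 * r$precision * r$recall / (r$precision + r$recall),
                 r$f1, tolerance = 2e-4, info = cl)
  }
  # weighted-average identity over the printed per-class rows
  expect_equal(sum(per$support * per$f1) / sum(per$support),
               tab$f1[tab$class == "weighted avg"], tolerance = 1e-4)
  # per-class supports sum to the printed micro support
  expect_equal(sum(per$support), unique(tab$support[grepl("avg", tab$class)]))
  rules <- ref_table("rules")
  per9 <- rules[!grepl("avg", rules$class), ]
  for (cl in c("PATIENT", "STR", "PHONE", "EMAIL")) {
    r <- per9[per9$class == cl, ]
    expect_equal(2 * r$precision * r$recall / (r$precision + r$recall),
                 r$f1, tolerance = 2e-4, info = cl)
  }
  expect_equal(sum(per9$support),
               unique(rules$support[grepl("avg", rules$class)]))
})

test_that("prf aggregates behave: macro bounds, degenerate flags", {
  counts <- data.frame(class = c("DATE", "ZIP", "EMAIL"),
                       tp = c(8L, 3L, 0L), fp = c(2L, 0L, 0L),
                       fn = c(1L, 2L, 4L))
  rep <- prf(counts)
  per <- rep[!grepl("avg", rep$class), ]
  macro <- rep$f1[rep$class == "macro avg"]
  expect_gte(macro, min(per$f1))
  expect_lte(macro, max(per$f1))
  # micro pools counts
  expect_equal(rep$precision[rep$class == "micro avg"], 11 / 13)
  # zero-denominator class flagged, metric 0
  expect_true(per$degenerate[per$class == "EMAIL"])
  expect_equal(per$precision[per$class == "EMAIL"], 0)
  # fully empty counts
  empty <- prf(data.frame(class = "DATE", tp = 0L, fp = 0L, fn = 0L),
               drop_empty = FALSE)
  expect_true(all(empty$f1 == 0))
  expect_true(all(empty$degenerate))
})
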