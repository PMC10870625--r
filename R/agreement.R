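# Multi-annotator concordance: Fleiss kappa over token labels, per-tag
# one-vs-rest kappas, pairwise agreement, bootstrap confidence intervals.
#
# Ratings are exchanged as a long data frame with columns `doc`, `item`
# (token identifier, unique within doc), `rater`, `label`; labels are the
# eight PII categories plus "O" for tokens outside any entity.

#' Build a rating count matrix
#'
#' Converts long-format ratings to the items-by-categories count matrix
#' Fleiss kappa operates on. Only items rated by exactly `n_raters` raters
#' are kept (the statistic requires a constant number of ratings per
#' item).
#'
#' @param ratings Long data frame with columns `doc`, `item`, `rater`,
#'   `label`.
#' @param n_raters Required ratings per item; defaults to the number of
#'   distinct raters present.
#' @return Integer matrix, one row per item, one column per label, each
#'   row summing to `n_raters`.
#' @export
rating_matrix <- function(ratings, n_raters = NULL) {
  stopifnot(all(c("doc", "item", "rater", "label") %in% names(ratings)))
  if (is.null(n_raters)) n_raters <- length(unique(ratings$rater))
  key <- paste(ratings$doc, ratings$item, sep = "\r")
  counts <- table(key, ratings$label)
  full <- rowSums(counts) == n_raters
  m <- matrix(as.integer(counts[full, , drop = FALSE]),
              nrow = sum(full), dimnames = dimnames(counts[full, , drop = FALSE]))
  m
}

#' Fleiss kappa
#'
#' Chance-corrected agreement for `n` raters assigning `k` categories to
#' `N` items: `kappa = (Pbar - Pe) / (1 - Pe)`, where `Pbar` is the mean
#' observed pairwise agreement per item and `Pe` the chance agreement
#' implied by the category marginals. When every rating falls in a single
#' category, `Pe = 1` and kappa is defined as 1 (the degenerate
#' perfect-agreement case), flagged via the `"degenerate"` attribute.
#'
#' @param x Items-by-categories count matrix (each row summing to the
#'   common number of raters), or a long ratings data frame accepted by
#'   [rating_matrix()].
#' @return Kappa in `[-1, 1]`.
#' @export
#' @examples
#' m <- rbind(c(3, 0), c(0, 3), c(3, 0))  # 3 raters, unanimous
#' fleiss_kappa(m)
fleiss_kappa <- function(x) {
  if (is.data.frame(x)) x <- rating_matrix(x)
  stopifnot(is.matrix(x), nrow(x) >= 1L)
  n <- sum(x[1L, ])
  if (n < 2L || any(rowSums(x) != n)) {
    stop("each item must be rated by the same number (>= 2) of raters",
         call. = FALSE)
  }
  N <- nrow(x)
  p_j <- colSums(x) / (N * n)
  P_i <- (rowSums(x^2) - n) / (n * (n - 1))
  P_bar <- mean(P_i)
  P_e <- sum(p_j^2)
  if (1 - P_e < .Machine$double.eps) {
    return(structure(1, degenerate = TRUE))
  }
  (P_bar - P_e) / (1 - P_e)
}

#' Per-tag Fleiss kappa
#'
#' Agreement for one tag, computed as Fleiss kappa on the binary
#' tag-versus-rest reduction of the token labels.
#'
#' @param ratings Long ratings data frame (see [rating_matrix()]).
#' @param tag Label to isolate (one of the PII categories or `"O"`).
#' @return Kappa in `[-1, 1]`.
#' @export
per_tag_kappa <- function(ratings, tag) {
  r <- ratings
  r$label <- ifelse(r$label == tag, tag, "OTHER")
  fleiss_kappa(r)
}

#' Pairwise agreement matrix
#'
#' Two-rater Fleiss kappa (equivalently Scott's pi) for every rater pair,
#' computed over the items both raters labeled. Pairs sharing no document
#' are reported as `NA`. The diagonal is 1.
#'
#' @param ratings Long ratings data frame (see [rating_matrix()]).
#' @param reps Bootstrap replicates for per-pair confidence intervals;
#'   0 (default) skips interval estimation.
#' @param level,seed Passed to [kappa_ci()] when `reps > 0`.
#' @return List with `kappa` (symmetric matrix), and when `reps > 0`,
#'   `ci_low` and `ci_high` matrices.
#' @export
pairwise_agreement <- function(ratings, reps = 0L, level = 0.95, seed = 1L) {
  raters <- sort(unique(ratings$rater))
  k <- length(raters)
  kap <- matrix(NA_real_, k, k, dimnames = list(raters, raters))
  lo <- hi <- if (reps > 0L) kap else NULL
  diag(kap) <- 1
  if (!is.null(lo)) { diag(lo) <- 1; diag(hi) <- 1 }
  for (a in seq_len(k - 1L)) {
    for (b in (a + 1L):k) {
      sub <- ratings[ratings$rater %in% raters[c(a, b)], , drop = FALSE]
      shared <- intersect(sub$doc[sub$rater == raters[a]],
                          sub$doc[sub$rater == raters[b]])
      if (!length(shared)) next
      sub <- sub[sub$doc %in% shared, , drop = FALSE]
      kap[a, b] <- kap[b, a] <- fleiss_kappa(rating_matrix(sub, 2L))
      if (reps > 0L) {
        ci <- kappa_ci(sub, level = level, reps = reps,
                       seed = seed + a * 131L + b, n_raters = 2L)
        lo[a, b] <- lo[b, a] <- ci[1L]
        hi[a, b] <- hi[b, a] <- ci[2L]
      }
    }
  }
  out <- list(kappa = kap)
  if (reps > 0L) { out$ci_low <- lo; out$ci_high <- hi }
  out
}

#' Bootstrap confidence interval for Fleiss kappa
#'
#' Percentile bootstrap resampling whole documents (the natural
#' exchangeable unit of an annotation campaign), deterministic given
#' `seed`.
#'
#' @param ratings Long ratings data frame (see [rating_matrix()]).
#' @param level Confidence level (default 0.95).
#' @param reps Bootstrap replicates (>= 100; default 1000).
#' @param seed Integer seed.
#' @param n_raters Passed to [rating_matrix()].
#' @return Numeric vector `c(low, high)`.
#' @export
kappa_ci <- function(ratings, level = 0.95, reps = 1000L, seed = 1L,
                     n_raters = NULL) {
  if (reps < 100L) stop("reps must be at least 100", call. = FALSE)
  docs <- unique(ratings$doc)
  by_doc <- split(seq_len(nrow(ratings)), ratings$doc)
  stats_ <- local_seed(seed, {
    vapply(seq_len(reps), function(r) {
      take <- sample(docs, length(docs), replace = TRUE)
      idx <- unlist(by_doc[as.character(take)], use.names = FALSE)
      boot <- ratings[idx, , drop = FALSE]
      # resampled copies of a document must count as distinct documents
      boot$doc <- rep(seq_along(take),
                      lengths(by_doc[as.character(take)]))
      m <- rating_matrix(boot, n_raters)
      if (nrow(m) == 0L) return(NA_real_)
      as.numeric(fleiss_kappa(m))
    }, numeric(1))
  })
  alpha <- (1 - level) / 2
  as.numeric(stats::quantile(stats_, c(alpha, 1 - alpha), na.rm = TRUE,
                             names = FALSE))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Token-label ratings from annotated corpora
#'
#' Builds the long ratings frame from several raters' versions of the
#' same sentences: each rater contributes, per token, either the category
#' of the mention covering it or `"O"`.
#'
#' @param corpora Named list (one element per rater) of corpora (lists of
#'   [corpus_record()]), positionally aligned across raters.
#' @param doc_ids Optional document identifier per sentence; defaults to
#'   each sentence's `doc_ref`.
#' @return Long data frame with columns `doc`, `item`, `rater`, `label`.
#' @export
ratings_from_corpora <- function(corpora, doc_ids = NULL) {
  stopifnot(length(corpora) >= 2L, !is.null(names(corpora)))
  out <- list()
  for (rater in names(corpora)) {
    corpus <- corpora[[rater]]
    for (s in seq_along(corpus)) {
      rec <- corpus[[s]]
      n <- nrow(rec$sent$tokens)
      if (n == 0L) next
      lab <- rep("O", n)
      m <- rec$mentions
      for (k in seq_len(nrow(m))) {
        lab[(m$token_first[k] + 1L):(m$token_last[k] + 1L)] <- m$category[k]
      }
      doc <- if (!is.null(doc_ids)) doc_ids[s] else rec$sent$doc_ref
      out[[length(out) + 1L]] <- data.frame(
        doc = doc, item = paste(s, seq_len(n) - 1L, sep = ":"),
        rater = rater, label = lab, stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}
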