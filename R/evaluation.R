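# Entity-level NER scoring: confusion counts from mention sets, per-class
# and micro/macro/weighted precision, recall and F1.

check_no_overlap <- function(m, what) {
  if (nrow(m) <= 1L) return(invisible())
  m <- m[order(m$char_start), , drop = FALSE]
  if (any(m$char_start[-1L] < m$char_end[-nrow(m)])) {
    stop("overlapping mentions in ", what, " set", call. = FALSE)
  }
  invisible()
}

as_mention_list <- function(x) {
  if (is.data.frame(x)) return(list(x))
  if (inherits(x, "corpus_record")) return(list(x$mentions))
  lapply(x, function(e) {
    if (inherits(e, "corpus_record")) e$mentions else e
  })
}

#' Confusion counts between gold and predicted mentions
#'
#' Strict mode: a predicted mention counts as a true positive iff its
#' category, start and end offsets all equal a gold mention, matched
#' one-to-one in position order. Token mode: counts are over per-token
#' category labels (a partially overlapping prediction earns partial
#' credit).
#'
#' @param gold,pred Mention data frames, lists of mention data frames
#'   (one per sentence), or lists of [corpus_record()] objects. Lists must
#'   be positionally aligned.
#' @param mode `"strict"` (default) or `"token"`.
#' @return Data frame of class `confusion_counts`: one row per category
#'   with columns `class`, `tp`, `fp`, `fn`, `support` (= tp + fn).
#' @export
#' @examples
#' g <- entity_mentions("DATE", 0L, 0L, 0L, 10L, "manual", "")
#' p <- entity_mentions("DATE", 0L, 0L, 0L, 10L, "pattern", "")
#' match_mentions(g, p)
match_mentions <- function(gold, pred, mode = c("strict", "token")) {
  mode <- match.arg(mode)
  gold <- as_mention_list(gold)
  pred <- as_mention_list(pred)
  if (length(gold) != length(pred)) {
    stop("gold and pred must have the same number of units", call. = FALSE)
  }
  cats <- pii_categories()
  tp <- fp <- fn <- stats::setNames(integer(length(cats)), cats)
  for (u in seq_along(gold)) {
    g <- gold[[u]]; p <- pred[[u]]
    check_no_overlap(g, "gold"); check_no_overlap(p, "pred")
    extra <- setdiff(unique(c(g$category, p$category)), cats)
    if (length(extra)) assert_category(extra)
    if (mode == "strict") {
      gk <- paste(g$category, g$char_start, g$char_end)
      pk <- paste(p$category, p$char_start, p$char_end)
      for (cl in unique(c(g$category, p$category))) {
        gsub_ <- gk[g$category == cl]
        psub_ <- pk[p$category == cl]
        n_match <- sum(!is.na(match(psub_, gsub_)))
        tp[cl] <- tp[cl] + n_match
        fp[cl] <- fp[cl] + length(psub_) - n_match
        fn[cl] <- fn[cl] + length(gsub_) - n_match
      }
    } else {
      glab <- token_labels(g)
      plab <- token_labels(p)
      idx <- union(names(glab), names(plab))
      gl <- glab[idx]; pl <- plab[idx]
      for (cl in unique(c(g$category, p$category))) {
        gi <- !is.na(gl) & gl == cl
        pi <- !is.na(pl) & pl == cl
        tp[cl] <- tp[cl] + sum(gi & pi)
        fp[cl] <- fp[cl] + sum(pi & !gi)
        fn[cl] <- fn[cl] + sum(gi & !pi)
      }
    }
  }
  structure(
    data.frame(class = cats, tp = as.integer(tp), fp = as.integer(fp),
               fn = as.integer(fn), support = as.integer(tp + fn),
               stringsAsFactors = FALSE, row.names = NULL),
    class = c("confusion_counts", "data.frame")
  )
}

# Per-token category labels of one mention set, named by token index.
token_labels <- function(m) {
  if (!nrow(m)) return(stats::setNames(character(), character()))
  idx <- unlist(mapply(seq, m$token_first, m$token_last, SIMPLIFY = FALSE))
  lab <- rep(m$category, m$token_last - m$token_first + 1L)
  stats::setNames(lab, as.character(idx))
}

f1_score <- function(p, r) ifelse(p + r > 0, 2 * p * r / (p + r), 0)

#' Precision/recall/F1 report from confusion counts
#'
#' Per-class metrics plus three aggregates: micro (metrics of the pooled
#' counts), macro (unweighted mean of per-class metrics) and weighted
#' (support-weighted mean of per-class metrics). A zero denominator
#' defines the metric as 0 and flags the row.
#'
#' @param counts A `confusion_counts` data frame from [match_mentions()],
#'   or any data frame with columns `class`, `tp`, `fp`, `fn`.
#' @param drop_empty Drop classes with `tp + fp + fn = 0` before
#'   aggregation (default `TRUE`).
#' @return Data frame of class `eval_report` with columns `class`,
#'   `precision`, `recall`, `f1`, `support`, `degenerate`; the last three
#'   rows are `micro avg`, `macro avg` and `weighted avg`.
#' @export
prf <- function(counts, drop_empty = TRUE) {
  stopifnot(all(c("class", "tp", "fp", "fn") %in% names(counts)))
  if (drop_empty) {
    counts <- counts[counts$tp + counts$fp + counts$fn > 0L, , drop = FALSE]
  }
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  rec <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  supp <- tp + fn
  per <- data.frame(
    class = counts$class, precision = prec, recall = rec,
    f1 = f1_score(prec, rec), support = supp,
    degenerate = (tp + fp == 0L) | (tp + fn == 0L),
    stringsAsFactors = FALSE
  )
  TP <- sum(tp); FP <- sum(fp); FN <- sum(fn)
  micro_p <- if (TP + FP > 0) TP / (TP + FP) else 0
  micro_r <- if (TP + FN > 0) TP / (TP + FN) else 0
  n_cl <- nrow(per)
  w <- if (sum(supp) > 0) supp / sum(supp) else rep(0, n_cl)
  agg <- data.frame(
    class = c("micro avg", "macro avg", "weighted avg"),
    precision = c(micro_p,
                  if (n_cl) mean(per$precision) else 0,
                  sum(w * per$precision)),
    recall = c(micro_r,
               if (n_cl) mean(per$recall) else 0,
               sum(w * per$recall)),
    f1 = c(f1_score(micro_p, micro_r),
           if (n_cl) mean(per$f1) else 0,
           sum(w * per$f1)),
    support = rep(sum(supp), 3L),
    degenerate = rep(TP + FP + FN == 0L, 3L),
    stringsAsFactors = FALSE
  )
  structure(rbind(per, agg), class = c("eval_report", "data.frame"))
}

#' @export
print.eval_report <- function(x, digits = 4, ...) {
  y <- x
  for (cl in c("precision", "recall", "f1")) y[[cl]] <- round(y[[cl]], digits)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' Score predicted annotations against gold annotations
#'
#' Convenience wrapper: aligns two corpora (lists of [corpus_record()]),
#' runs [match_mentions()] and [prf()].
#'
#' @param gold,pred Corpora (lists of [corpus_record()]), positionally
#'   aligned.
#' @param mode Matching criterion, see [match_mentions()].
#' @return An `eval_report` data frame.
#' @export
evaluate_annotations <- function(gold, pred, mode = c("strict", "token")) {
  prf(match_mentions(gold, pred, match.arg(mode)))
}
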