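# Apply mentions back onto the original HTML through the offset map.

#' Masking policy
#'
#' @param mode `"placeholder"` (replace each PII span with
#'   `[<CATEGORY>]`) or `"surrogate"` (replace with a same-category
#'   realistic value drawn from the synthetic samplers).
#' @param template Placeholder template; `"CATEGORY"` is substituted by
#'   the mention category.
#' @param seed Seed of the surrogate sampler.
#' @return An object of class `mask_policy`.
#' @export
mask_policy <- function(mode = c("placeholder", "surrogate"),
                        template = "[CATEGORY]", seed = 1L) {
  structure(list(mode = match.arg(mode), template = template,
                 seed = as.integer(seed)),
            class = "mask_policy")
}

# Collect the source ranges covered by an extracted-text range, split into
# maximal runs of contiguous source characters (a range crossing markup is
# masked piecewise, leaving the markup untouched).
source_runs <- function(map, ext_start, ext_end) {
  idx <- seq.int(ext_start + 1L, ext_end)  # 1-based into map vectors
  s <- map$src_start[idx]; e <- map$src_end[idx]
  real <- e > s  # drop zero-width synthesised characters
  s <- s[real]; e <- e[real]
  if (!length(s)) return(data.frame(start = integer(), end = integer()))
  brk <- c(TRUE, s[-1L] != e[-length(e)])
  grp <- cumsum(brk)
  data.frame(start = tapply(s, grp, min), end = tapply(e, grp, max))
}

#' Mask PII in the original document
#'
#' Replaces each mention's source character range in the raw document,
#' leaving every character outside the masked ranges untouched. A mention
#' whose extracted span crosses a tag boundary is masked piecewise so the
#' markup survives. In placeholder mode the operation is idempotent
#' (placeholders match no detector); in surrogate mode the replacement is
#' guaranteed to differ from the masked surface.
#'
#' @param doc A [source_document()] (or a raw string).
#' @param spans Data frame of extracted-text spans to mask, with columns
#'   `start`, `end` (0-based half-open, document-level extracted offsets)
#'   and `category`; see [doc_level_spans()].
#' @param map The `offset_map` from [parse_html()]/[parse_document()] for
#'   this document.
#' @param policy A [mask_policy()].
#' @return Masked raw document (character scalar).
#' @export
mask_document <- function(doc, spans, map, policy = mask_policy()) {
  raw <- if (inherits(doc, "source_document")) doc$raw else doc
  if (is.null(spans) || nrow(spans) == 0L) return(raw)
  runs <- do.call(rbind, lapply(seq_len(nrow(spans)), function(k) {
    r <- source_runs(map, spans$start[k], spans$end[k])
    if (nrow(r)) r$category <- spans$category[k]
    r
  }))
  if (is.null(runs) || nrow(runs) == 0L) return(raw)
  runs <- runs[order(-runs$start), , drop = FALSE]
  out <- raw
  for (k in seq_len(nrow(runs))) {
    surface <- substr(out, runs$start[k] + 1L, runs$end[k])
    repl <- if (policy$mode == "placeholder") {
      gsub("CATEGORY", runs$category[k], policy$template, fixed = TRUE)
    } else {
      surrogate_value(runs$category[k], surface,
                      policy$seed + runs$start[k])
    }
    out <- paste0(substr(out, 1L, runs$start[k]), repl,
                  substring(out, runs$end[k] + 1L))
  }
  out
}

#' Document-level spans of sentence mentions
#'
#' Lifts sentence-local mention offsets to extracted-document offsets,
#' ready for [mask_document()].
#'
#' @param sentences List of [sentence()] objects (as from
#'   [parse_document()]).
#' @param mentions_list Positionally aligned list of mention data frames.
#' @return Data frame with columns `start`, `end`, `category`.
#' @export
doc_level_spans <- function(sentences, mentions_list) {
  stopifnot(length(sentences) == length(mentions_list))
  out <- lapply(seq_along(sentences), function(i) {
    m <- mentions_list[[i]]
    if (is.null(m) || nrow(m) == 0L) return(NULL)
    data.frame(start = sentences[[i]]$text_offset + m$char_start,
               end = sentences[[i]]$text_offset + m$char_end,
               category = m$category, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(start = integer(), end = integer(),
                      category = character(), stringsAsFactors = FALSE)
  }
  out
}
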