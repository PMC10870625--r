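# End-to-end distant-supervision pipeline: ingest -> annotate -> filter ->
# patient-level split -> JSONL/CoNLL artifacts + statistics.

#' Annotate a set of documents with the rule cascade
#'
#' Parses each document, builds its metadata keys and annotates every
#' sentence, producing one [corpus_record()] per sentence.
#'
#' @param docs List of [source_document()] objects.
#' @param gazetteers Named list of [gazetteer()] objects (`DOCTOR`,
#'   `STR`, `ZIP`, `VILLE`).
#' @param cfg A [rule_config()].
#' @return List of [corpus_record()] objects in document, then sentence,
#'   order.
#' @export
annotate_documents <- function(docs, gazetteers = list(),
                               cfg = rule_config()) {
  out <- list()
  for (doc in docs) {
    parsed <- parse_document(doc)
    keys <- patient_record_keys(doc, cfg)
    for (sent in parsed$sentences) {
      mentions <- annotate_sentence(sent, cfg, gazetteers, keys)
      out[[length(out) + 1L]] <- corpus_record(
        sent, mentions,
        meta = list(ID_PAT = doc$patient_id, ID_ENTREPOT = doc$doc_id,
                    CODE = doc$dialect)
      )
    }
  }
  out
}

#' Run the full distant-supervision pipeline
#'
#' Executes ingest, gazetteer loading, rule annotation, entity-sentence
#' filtering and the patient-level 80/10/10 split, optionally writing one
#' JSONL and one CoNLL file per partition plus a statistics report.
#'
#' @param docs List of [source_document()] objects.
#' @param gazetteers Named list of [gazetteer()] objects, or a named list
#'   of file paths `list(ban = ..., rpps = ...)` to load with
#'   [load_ban()] / [load_health_directory()].
#' @param cfg A [rule_config()].
#' @param ratios Train/valid/test ratios (sum 1).
#' @param seed Split seed.
#' @param out_dir Output directory; `NULL` skips file output.
#' @return List with `partitions` (named list of corpus-record lists),
#'   `split` (the `split_assignment`), `stats` (per-partition and total
#'   [corpus_stats()]), and `files` (paths written, if any).
#' @export
run_distant_supervision <- function(docs, gazetteers = list(),
                                    cfg = rule_config(),
                                    ratios = c(0.8, 0.1, 0.1), seed = 42L,
                                    out_dir = NULL) {
  if (!is.null(gazetteers$ban) && is.character(gazetteers$ban)) {
    loaded <- load_ban(gazetteers$ban)
    doctor <- if (!is.null(gazetteers$rpps)) {
      load_health_directory(gazetteers$rpps)
    }
    gazetteers <- c(loaded, list(DOCTOR = doctor))
  }
  records <- annotate_documents(docs, gazetteers, cfg)
  records <- filter_sentences(records)
  pat <- vapply(records, function(r) as.character(r$meta$ID_PAT), character(1))
  split <- split_by_patient(pat, ratios, seed)
  part_of <- unname(split[pat])
  partitions <- lapply(c(train = "train", valid = "valid", test = "test"),
                       function(p) records[part_of == p])
  stats <- c(lapply(partitions, corpus_stats),
             list(total = corpus_stats(records)))
  files <- list()
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    for (p in names(partitions)) {
      jp <- file.path(out_dir, paste0(p, ".jsonl"))
      cp <- file.path(out_dir, paste0(p, ".conll"))
      write_jsonl(partitions[[p]], jp)
      write_conll(partitions[[p]], cp)
      files[[p]] <- c(jsonl = jp, conll = cp)
    }
    sp <- file.path(out_dir, "stats.tsv")
    tab <- do.call(rbind, lapply(names(stats), function(nm) {
      data.frame(partition = nm, n_sentences = stats[[nm]]$n_sentences,
                 t(stats[[nm]]$counts), stringsAsFactors = FALSE)
    }))
    utils::write.table(tab, sp, sep = "\t", row.names = FALSE, quote = FALSE)
    files$stats <- sp
  }
  list(partitions = partitions, split = split, stats = stats, files = files)
}
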