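# End-to-end workflows tying the modules together: de-identify a record or a
# corpus, and evaluate predictions against gold standoff files.

#' De-identify one record
#'
#' Normalizes textual month dates, scans for PHI (patterns, lexicons, context
#' rules, protections, do-not-remove override), and replaces each detected
#' span with a surrogate or category tag. Dates other than the structured
#' date of birth are preserved.
#'
#' @param record a `Record`
#' @param lexset compiled `LexiconSet`
#' @param config an [engine_config()]
#' @param prep internal: pre-computed lexicon preparation
#' @param seed surrogate seed (defaults to `config$seed`)
#' @return a `DeidResult` (see [replace_phi()]); the annotations refer to the
#'   month-normalized text, which is also attached as `scanned_text`
#' @export
deidentify_record <- function(record, lexset, config = engine_config(),
                              prep = NULL, seed = NULL) {
  norm <- normalize_month_dates(record$text)
  record$text <- norm$text
  ann <- phi_scan(record, lexset, config, prep = prep)
  res <- replace_phi(record, ann, lexset, seed = seed %||% config$seed,
                     mode = config$surrogate_mode)
  res$scanned_text <- norm$text
  res$normalization_edits <- norm$edits
  res
}

#' De-identify a corpus
#'
#' @param corpus a corpus list (from [generate_corpus()] or [read_corpus()])
#'   or a directory path
#' @param lexset compiled `LexiconSet`
#' @param config an [engine_config()]
#' @param out_dir optional directory: writes de-identified `records/<id>.txt`,
#'   predicted annotations `pred/<id>.tsv`, and a run manifest
#' @return named list of `DeidResult` objects, invisibly when writing
#' @export
deidentify_corpus <- function(corpus, lexset, config = engine_config(),
                              out_dir = NULL) {
  if (is.character(corpus)) corpus <- read_corpus(corpus)
  prep <- prepare_lexicons(lexset)
  ids <- names(corpus$records)
  results <- lapply(seq_along(ids), function(i) {
    deidentify_record(corpus$records[[ids[i]]], lexset, config, prep = prep,
                      seed = config$seed + i)
  })
  names(results) <- ids
  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "records"), recursive = TRUE,
               showWarnings = FALSE)
    dir.create(file.path(out_dir, "pred"), recursive = TRUE,
               showWarnings = FALSE)
    for (id in ids) {
      writeLines(results[[id]]$text,
                 file.path(out_dir, "records", paste0(id, ".txt")),
                 useBytes = TRUE)
      write_standoff(results[[id]]$annotations, id,
                     file.path(out_dir, "pred", paste0(id, ".tsv")))
    }
    manifest <- list(seed = config$seed, mode = config$surrogate_mode,
                     lexicon_checksum = lexset$checksum,
                     n_records = length(ids),
                     n_annotations = sum(vapply(results, function(r)
                       nrow(r$annotations), integer(1))))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    return(invisible(results))
  }
  results
}

#' Evaluate predicted annotations against gold standoff files
#'
#' @param corpus corpus list or directory (texts + gold)
#' @param pred named list of annotation data.frames, a directory of standoff
#'   TSVs, or a named list of `DeidResult`s
#' @param exclude_punctuation see [align_tokens()]
#' @return see [evaluate_corpus()]
#' @export
evaluate_predictions <- function(corpus, pred, exclude_punctuation = TRUE) {
  if (is.character(corpus)) corpus <- read_corpus(corpus)
  if (is.character(pred)) {
    files <- list.files(pred, pattern = "\\.tsv$", full.names = TRUE)
    pred <- stats::setNames(lapply(files, read_standoff),
                            tools::file_path_sans_ext(basename(files)))
  } else if (length(pred) && inherits(pred[[1]], "DeidResult")) {
    pred <- lapply(pred, `[[`, "annotations")
  }
  evaluate_corpus(corpus$records, corpus$gold, pred,
                  exclude_punctuation = exclude_punctuation)
}
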