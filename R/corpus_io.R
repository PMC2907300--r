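# On-disk corpus dialects: one UTF-8 text file per record, a delimited
# sidecar table for the structured fields, and tab-separated standoff
# annotation files (record_id, start, end, category, rule_id, surface) with
# 0-based half-open offsets.

#' Write standoff annotations to a TSV file
#'
#' @param ann annotation data.frame
#' @param record_id record identifier written in the first column
#' @param path output file
#' @return `path`, invisibly
#' @export
write_standoff <- function(ann, record_id, path) {
  df <- data.frame(record_id = rep(record_id, nrow(ann)),
                   ann[, c("start", "end", "category", "rule_id", "surface")],
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read standoff annotations from a TSV file
#'
#' @param path a TSV written by [write_standoff()]
#' @return annotation data.frame (record ids dropped; one file per record)
#' @export
read_standoff <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = c(record_id = "character",
                                         start = "integer", end = "integer",
                                         category = "character",
                                         rule_id = "character",
                                         surface = "character"),
                          quote = "", encoding = "UTF-8")
  df[, c("start", "end", "category", "rule_id", "surface")]
}

read_text_file <- function(path) {
  paste(readLines(path, encoding = "UTF-8", warn = FALSE), collapse = "\n")
}

#' Write a generated corpus to disk
#'
#' @param corpus result of [generate_corpus()]
#' @param dir output directory
#' @return `dir`, invisibly
#' @export
write_corpus <- function(corpus, dir) {
  for (d in c("records", "gold", "decoys")) {
    dir.create(file.path(dir, d), recursive = TRUE, showWarnings = FALSE)
  }
  for (id in names(corpus$records)) {
    writeLines(corpus$records[[id]]$text,
               file.path(dir, "records", paste0(id, ".txt")), useBytes = TRUE)
    write_standoff(corpus$gold[[id]], id,
                   file.path(dir, "gold", paste0(id, ".tsv")))
    utils::write.table(corpus$decoys[[id]],
                       file.path(dir, "decoys", paste0(id, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
  }
  utils::write.table(corpus$sidecar, file.path(dir, "sidecar.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  texts <- vapply(corpus$records, `[[`, character(1), "text")
  manifest <- list(
    n_records = corpus$spec$n_records,
    seed = corpus$spec$seed,
    note_type_mix = as.list(corpus$spec$note_type_mix),
    phi_density = as.list(corpus$spec$phi_density),
    decoy_density = corpus$spec$decoy_density,
    ambiguity_rate = corpus$spec$ambiguity_rate,
    checksum = content_checksum(paste(names(texts), texts, sep = "\t"))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read a corpus from disk
#'
#' Reads `records/*.txt` plus `sidecar.tsv` into `Record` objects, and gold
#' annotations when present.
#'
#' @param dir corpus directory ([write_corpus()] layout)
#' @return list with `records`, `gold` (possibly empty), `sidecar`
#' @export
read_corpus <- function(dir) {
  sidecar <- utils::read.delim(file.path(dir, "sidecar.tsv"), sep = "\t",
                               stringsAsFactors = FALSE, quote = "",
                               colClasses = "character")
  records <- lapply(seq_len(nrow(sidecar)), function(i) {
    row <- sidecar[i, ]
    new_record(row$record_id,
               read_text_file(file.path(dir, "records",
                                        paste0(row$record_id, ".txt"))),
               note_type = row$note_type,
               patient_first = row$patient_first,
               patient_last = row$patient_last,
               provider_first = if (is.na(row$provider_first)) NA_character_
                                else row$provider_first,
               provider_last = row$provider_last,
               gender = row$gender, dob = as.Date(row$dob))
  })
  names(records) <- sidecar$record_id
  gold <- list()
  gold_dir <- file.path(dir, "gold")
  if (dir.exists(gold_dir)) {
    for (f in list.files(gold_dir, pattern = "\\.tsv$", full.names = TRUE)) {
      gold[[tools::file_path_sans_ext(basename(f))]] <- read_standoff(f)
    }
  }
  list(records = records, gold = gold, sidecar = sidecar)
}
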