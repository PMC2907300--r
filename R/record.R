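# Record container: one free-text note plus its structured sidecar fields.

note_types <- function() {
  c("progress_note", "consult_letter", "referral_letter", "discharge_summary",
    "diagnostic_report", "cpp_entry")
}

#' Construct a Record
#'
#' @param record_id unique identifier within a corpus
#' @param text the free-text note (may be empty, not NULL)
#' @param note_type one of [note_types()]
#' @param patient_first,patient_last structured patient name
#' @param provider_first,provider_last structured provider name
#' @param gender `"M"`, `"F"` or `"U"`
#' @param dob structured date of birth (`Date` or ISO string), or `NA`
#' @return object of class `Record`
#' @export
new_record <- function(record_id, text, note_type = "progress_note",
                       patient_first = NA_character_,
                       patient_last = NA_character_,
                       provider_first = NA_character_,
                       provider_last = NA_character_,
                       gender = c("U", "M", "F"), dob = NA) {
  note_type <- match.arg(note_type, note_types())
  gender <- match.arg(toupper(gender), c("U", "M", "F"))
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  if (!is.na(dob[1])) dob <- as.Date(dob)
  structure(list(record_id = as.character(record_id), text = text,
                 note_type = note_type,
                 patient_first = patient_first, patient_last = patient_last,
                 provider_first = provider_first, provider_last = provider_last,
                 gender = gender, dob = dob),
            class = "Record")
}

#' @export
print.Record <- function(x, ...) {
  cat(sprintf("<Record %s (%s), %d chars>\n", x$record_id, x$note_type,
              nchar(x$text)))
  invisible(x)
}
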