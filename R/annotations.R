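# PHI annotation containers: plain data.frames with 0-based half-open
# character offsets, the standoff convention used by the on-disk TSV dialect.

#' PHI categories recognized by the engine
#' @export
phi_categories <- function() {
  c("patient_name", "provider_name", "facility", "street", "municipality",
    "business", "health_card_number", "postal_code", "phone_number",
    "medical_record_number", "web_email", "date_of_birth")
}

# Overlap-resolution priority (smaller = stronger). More structured patterns
# are more reliable; date-of-birth is structured-field driven and strongest.
category_priority <- function(category) {
  order <- c("date_of_birth", "health_card_number", "postal_code",
             "phone_number", "medical_record_number", "patient_name",
             "provider_name", "facility", "street", "municipality",
             "business", "web_email")
  match(category, order, nomatch = length(order) + 1L)
}

#' Construct a PHI annotation set
#'
#' @param start,end integer vectors, 0-based half-open character offsets
#' @param category PHI category (see [phi_categories()])
#' @param rule_id identifier of the producing rule
#' @param text the source text; used to compute `surface` when not given
#' @param surface matched substrings (computed from `text` if `NULL`)
#' @return data.frame with columns start, end, category, rule_id, surface
#' @export
new_annotations <- function(start = integer(), end = integer(),
                            category = character(), rule_id = character(),
                            text = NULL, surface = NULL) {
  start <- as.integer(start)
  end <- as.integer(end)
  n <- length(start)
  if (n > 0L) {
    stopifnot(length(end) == n, all(start >= 0L), all(end > start))
    if (is.null(surface)) {
      stopifnot(!is.null(text))
      surface <- substring(text, start + 1L, end)
    }
    category <- rep_len(as.character(category), n)
    rule_id <- rep_len(as.character(rule_id), n)
    bad <- setdiff(unique(category), phi_categories())
    if (length(bad)) stop("unknown PHI category: ", paste(bad, collapse = ", "))
  } else {
    surface <- character()
    category <- character()
    rule_id <- character()
  }
  data.frame(start = start, end = end, category = category,
             rule_id = rule_id, surface = surface, stringsAsFactors = FALSE)
}

#' @rdname new_annotations
#' @export
empty_annotations <- function() new_annotations()

# rbind a list of annotation frames, tolerating NULL/zero-row members.
bind_annotations <- function(...) {
  xs <- Filter(function(x) !is.null(x) && nrow(x) > 0L, list(...))
  if (!length(xs)) return(empty_annotations())
  do.call(rbind, c(xs, list(make.row.names = FALSE)))
}

# Assert annotations are in-bounds for text and internally consistent.
check_annotations <- function(ann, text) {
  if (nrow(ann) == 0L) return(invisible(TRUE))
  stopifnot(all(ann$start >= 0L), all(ann$end <= nchar(text)),
            all(ann$end > ann$start))
  stopifnot(identical(ann$surface, substring(text, ann$start + 1L, ann$end)))
  invisible(TRUE)
}
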