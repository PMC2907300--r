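# Small internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Case-fold a character vector
#' @param x character vector
#' @return lower-cased vector
#' @keywords internal
cf <- function(x) tolower(x)

# Strip a trailing possessive ("Homan's" -> "Homan"); straight or curly quote.
strip_possessive <- function(x) {
  sub("['’][sS]$", "", x, perl = TRUE)
}

#' Content digest over a set of entries
#'
#' Order-independent checksum: entries are sorted byte-wise before hashing so
#' the ordering of source files is irrelevant.
#'
#' @param lines character vector
#' @return md5 hex string
#' @export
content_checksum <- function(lines) {
  tmp <- tempfile(fileext = ".txt")
  on.exit(unlink(tmp), add = TRUE)
  con <- file(tmp, open = "wb")
  writeLines(sort(enc2utf8(as.character(lines)), method = "radix"), con,
             useBytes = TRUE)
  close(con)
  unname(tools::md5sum(tmp))
}

# Escape a literal string for use inside a PCRE pattern.
regex_escape <- function(x) gsub("([\\^$.|?*+()\\[\\]{}\\\\-])", "\\\\\\1", x, perl = TRUE)

# Vectorized overlap test between one span and a data.frame of spans
# (0-based half-open on both sides).
span_overlaps_any <- function(start, end, spans) {
  if (is.null(spans) || nrow(spans) == 0L) return(rep(FALSE, length(start)))
  vapply(seq_along(start), function(i) {
    any(start[i] < spans$end & spans$start < end[i])
  }, logical(1))
}
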