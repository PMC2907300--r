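# Whitespace/punctuation tokenizer with preserved character offsets.

# Word tokens are alphanumeric runs possibly joined by internal hyphens or
# apostrophes ("Operative-Smith", "Parkinson's"); every other non-space
# character is its own token. Offsets are 0-based half-open, so
# surface == substring(text, start + 1, end) and the gaps between consecutive
# tokens are whitespace only.
token_regex <- "[A-Za-z0-9]+(?:['’-][A-Za-z0-9]+)*|[^A-Za-z0-9\\s]"

#' Tokenize text, keeping character offsets
#'
#' Splits on whitespace with punctuation separated into its own tokens.
#' Hyphenated and possessive forms stay single tokens so the hyphenated-name
#' and eponym rules can inspect them whole.
#'
#' @param text a single string
#' @return data.frame with columns `start`, `end` (0-based half-open),
#'   `surface`, and `is_word` (contains an alphanumeric character)
#' @export
tokenize <- function(text) {
  stopifnot(length(text) == 1L)
  if (is.na(text) || !nzchar(text)) {
    return(data.frame(start = integer(), end = integer(),
                      surface = character(), is_word = logical(),
                      stringsAsFactors = FALSE))
  }
  m <- gregexpr(token_regex, text, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(data.frame(start = integer(), end = integer(),
                      surface = character(), is_word = logical(),
                      stringsAsFactors = FALSE))
  }
  start <- as.integer(m) - 1L
  len <- attr(m, "match.length")
  surface <- substring(text, start + 1L, start + len)
  data.frame(start = start, end = start + len, surface = surface,
             is_word = grepl("[A-Za-z0-9]", surface), stringsAsFactors = FALSE)
}
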