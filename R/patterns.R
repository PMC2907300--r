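# Numeric/structural PHI detectors and the clinical-content protections that
# veto spurious matches. All offsets are 0-based half-open; matches never
# cross a newline (separators inside patterns are literal spaces or hyphens).

match_all <- function(text, pattern) {
  m <- gregexpr(pattern, text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(data.frame(start = integer(), end = integer()))
  start <- as.integer(m) - 1L
  data.frame(start = start, end = start + attr(m, "match.length"))
}

#' Protected clinical nomenclature check
#'
#' True for tokens that look like identifiers but are standard clinical
#' shorthand: obstetric history `G#P#A#` (and `G#P#` prefixes), spinal-level
#' runs over the letters C/T/L/S (e.g. `C6C7T1`), and heart-sound runs such as
#' `S1S2S4`. Such tokens must never be scrubbed as postal codes.
#'
#' @param token a character vector of tokens
#' @return logical vector
#' @export
is_protected_nomenclature <- function(token) {
  token <- as.character(token)
  obst <- grepl("^[Gg][0-9]{1,2}[Pp][0-9]{1,2}([Aa][0-9]{1,2})?$", token)
  spinal <- grepl("^(?:[CTLSctls][0-9]{1,2}){2,}$", token, perl = TRUE)
  obst | spinal
}

#' Protected single-letter check
#'
#' Single alphabetic characters immediately followed by punctuation (the
#' "S. O. A. P." charting style) are never name candidates.
#'
#' @param token candidate token
#' @param following the text immediately after the token
#' @return logical
#' @export
is_protected_single_letter <- function(token, following) {
  nchar(token) == 1L & grepl("^[A-Za-z]$", token) &
    grepl("^[[:punct:]]", substr(following, 1L, 1L))
}

#' Find Canadian postal codes
#'
#' Letter-digit alternation (A1A 1A1, inner space optional), bounded by
#' non-alphanumerics. Matches whose compact form is protected clinical
#' nomenclature (see [is_protected_nomenclature()]) are vetoed.
#'
#' @param text a single string
#' @return annotation data.frame (category `postal_code`)
#' @export
find_postal_codes <- function(text) {
  pat <- "(?<![A-Za-z0-9])[A-Za-z][0-9][A-Za-z] ?[0-9][A-Za-z][0-9](?![A-Za-z0-9])"
  m <- match_all(text, pat)
  if (nrow(m) == 0L) return(empty_annotations())
  surf <- substring(text, m$start + 1L, m$end)
  keep <- !is_protected_nomenclature(gsub(" ", "", surf, fixed = TRUE))
  m <- m[keep, , drop = FALSE]
  new_annotations(m$start, m$end, "postal_code", "pat:postal_code", text)
}

#' Find calendar date mentions
#'
#' Numeric dates in `m/d/yyyy` (or the day-first reading) and ISO
#' `yyyy-mm-dd` form. Only strings that are valid under at least one reading
#' are date mentions; `06/31/2007` is not.
#'
#' @param text a single string
#' @return data.frame with `start`, `end`, `surface`
#' @export
find_date_mentions <- function(text) {
  out <- list()
  m <- match_all(text, "(?<![0-9/])[0-9]{1,2}/[0-9]{1,2}/[0-9]{4}(?![0-9/])")
  if (nrow(m)) {
    surf <- substring(text, m$start + 1L, m$end)
    parts <- strsplit(surf, "/", fixed = TRUE)
    ok <- vapply(parts, function(p) {
      a <- as.integer(p[1]); b <- as.integer(p[2]); y <- as.integer(p[3])
      valid_ymd(y, a, b) || valid_ymd(y, b, a)
    }, logical(1))
    out$slash <- cbind(m[ok, , drop = FALSE], surface = surf[ok])
  }
  m <- match_all(text, "(?<![0-9])[0-9]{4}-[0-9]{2}-[0-9]{2}(?![0-9])")
  if (nrow(m)) {
    surf <- substring(text, m$start + 1L, m$end)
    parts <- strsplit(surf, "-", fixed = TRUE)
    ok <- vapply(parts, function(p) {
      valid_ymd(as.integer(p[1]), as.integer(p[2]), as.integer(p[3]))
    }, logical(1))
    out$iso <- cbind(m[ok, , drop = FALSE], surface = surf[ok])
  }
  out <- Filter(function(x) !is.null(x) && nrow(x) > 0L, out)
  if (!length(out)) {
    return(data.frame(start = integer(), end = integer(), surface = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  res[order(res$start), , drop = FALSE]
}

valid_ymd <- function(y, m, d) {
  !is.na(y) & !is.na(m) & !is.na(d) & m >= 1L & m <= 12L & d >= 1L &
    d <= days_in_month(y, m)
}

days_in_month <- function(y, m) {
  dm <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
  out <- dm[ifelse(m >= 1L & m <= 12L, m, 1L)]
  leap <- (y %% 4 == 0 & y %% 100 != 0) | y %% 400 == 0
  ifelse(m == 2L & leap, 29L, out)
}

#' Find Ontario health card numbers
#'
#' Ten consecutive digits, or digits grouped 4-3-3 with space or hyphen
#' separators, optionally followed by a one- or two-letter (uppercase)
#' version code. Digit runs inside a detected calendar date are excluded.
#'
#' @param text a single string
#' @param dates optional pre-computed date mentions ([find_date_mentions()])
#' @return annotation data.frame (category `health_card_number`)
#' @export
find_health_card_numbers <- function(text, dates = NULL) {
  if (is.null(dates)) dates <- find_date_mentions(text)
  pats <- c(
    grouped = "(?<![0-9A-Za-z])[0-9]{4}[ -][0-9]{3}[ -][0-9]{3}(?:[ -]?[A-Z]{1,2})?(?![0-9A-Za-z])",
    plain = "(?<![0-9A-Za-z.])[0-9]{10}(?:[A-Z]{1,2})?(?![0-9A-Za-z.])"
  )
  res <- lapply(names(pats), function(nm) {
    m <- match_all(text, pats[[nm]])
    if (nrow(m) == 0L) return(NULL)
    m$rule <- paste0("pat:hcn_", nm)
    m
  })
  res <- Filter(Negate(is.null), res)
  if (!length(res)) return(empty_annotations())
  m <- do.call(rbind, res)
  # grouped matches may nest inside plain ones and vice versa; keep longest
  m <- m[order(-(m$end - m$start), m$start), , drop = FALSE]
  keep <- rep(TRUE, nrow(m))
  for (i in seq_len(nrow(m))) {
    if (!keep[i]) next
    later <- which(keep & seq_len(nrow(m)) > i)
    if (length(later)) {
      ov <- m$start[later] < m$end[i] & m$start[i] < m$end[later]
      keep[later[ov]] <- FALSE
    }
  }
  m <- m[keep, , drop = FALSE]
  m <- m[!span_overlaps_any(m$start, m$end, dates), , drop = FALSE]
  if (nrow(m) == 0L) return(empty_annotations())
  m <- m[order(m$start), , drop = FALSE]
  new_annotations(m$start, m$end, "health_card_number", m$rule, text)
}

phone_context_words <- c("tel", "telephone", "phone", "fax", "pager", "cell",
                         "mobile", "call")

#' Find phone numbers
#'
#' North-American shapes (optional leading 1, optional 3-digit area code with
#' or without parentheses, hyphen/space/dot separators) plus bare 7- or
#' 10-digit runs preceded within 10 characters by a context word such as
#' "tel", "fax", "pager" or "cell". The returned frame carries a `context`
#' column used to win precedence over health-card matches of the same digits.
#'
#' @param text a single string
#' @return annotation data.frame (category `phone_number`) with an extra
#'   logical `context` column
#' @export
find_phone_numbers <- function(text) {
  shaped <- "(?<![0-9A-Za-z])(?:1[ .-])?(?:\\([0-9]{3}\\)[ .-]?|[0-9]{3}[ .-])?[0-9]{3}[ .-][0-9]{4}(?![0-9A-Za-z])"
  bare <- "(?<![0-9A-Za-z.])(?:[0-9]{10}|[0-9]{7})(?![0-9A-Za-z.])"
  has_context <- function(start) {
    lo <- pmax(0L, start - 12L)
    win <- cf(substring(text, lo + 1L, start))
    grepl(paste0("(", paste(phone_context_words, collapse = "|"), ")[^a-z0-9]*$"),
          win, perl = TRUE)
  }
  ms <- match_all(text, shaped)
  mb <- match_all(text, bare)
  res <- list()
  if (nrow(ms)) {
    ms$rule <- "pat:phone_shaped"
    ms$context <- has_context(ms$start)
    res$s <- ms
  }
  if (nrow(mb)) {
    mb$context <- has_context(mb$start)
    mb <- mb[mb$context, , drop = FALSE]
    if (nrow(mb)) {
      mb$rule <- "pat:phone_context"
      res$b <- mb
    }
  }
  if (!length(res)) return(empty_annotations_phone())
  m <- do.call(rbind, res)
  # drop bare matches nested in shaped ones
  m <- m[order(-(m$end - m$start), m$start), , drop = FALSE]
  keep <- rep(TRUE, nrow(m))
  for (i in seq_len(nrow(m))) {
    if (!keep[i]) next
    later <- which(keep & seq_len(nrow(m)) > i)
    if (length(later)) {
      ov <- m$start[later] < m$end[i] & m$start[i] < m$end[later]
      keep[later[ov]] <- FALSE
    }
  }
  m <- m[keep, , drop = FALSE]
  m <- m[order(m$start), , drop = FALSE]
  ann <- new_annotations(m$start, m$end, "phone_number", m$rule, text)
  ann$context <- m$context
  ann
}

empty_annotations_phone <- function() {
  ann <- empty_annotations()
  ann$context <- logical()
  ann
}

#' Find medical record numbers
#'
#' Standalone digit runs of 5-9 digits, delimiter-separated (never embedded in
#' a longer alphanumeric token and never part of a decimal number), and not
#' already claimed by a date, health-card, phone or postal-code match.
#'
#' @param text a single string
#' @param claimed optional data.frame of spans (`start`, `end`) already
#'   claimed by stronger detectors
#' @return annotation data.frame (category `medical_record_number`)
#' @export
find_medical_record_numbers <- function(text, claimed = NULL) {
  pat <- "(?<![0-9A-Za-z])(?<![0-9]\\.)[0-9]{5,9}(?![0-9A-Za-z])(?!\\.[0-9])"
  m <- match_all(text, pat)
  if (nrow(m) == 0L) return(empty_annotations())
  if (is.null(claimed)) {
    claimed <- rbind(
      find_date_mentions(text)[, c("start", "end")],
      find_health_card_numbers(text)[, c("start", "end")],
      find_phone_numbers(text)[, c("start", "end")],
      find_postal_codes(text)[, c("start", "end")]
    )
  }
  m <- m[!span_overlaps_any(m$start, m$end, claimed), , drop = FALSE]
  new_annotations(m$start, m$end, "medical_record_number", "pat:mrn", text)
}

#' Find web addresses and email addresses
#'
#' Tokens containing `@` with a dotted domain, and tokens starting with a URL
#' scheme or `www.` followed by a dotted host.
#'
#' @param text a single string
#' @return annotation data.frame (category `web_email`)
#' @export
find_web_email <- function(text) {
  email <- "[A-Za-z0-9._%+-]+@[A-Za-z0-9-]+(?:\\.[A-Za-z0-9-]+)*\\.[A-Za-z]{2,}"
  url <- "(?:https?://|www\\.)[A-Za-z0-9-]+(?:\\.[A-Za-z0-9-]+)*\\.[A-Za-z]{2,}(?:/[^[:space:]]*)?"
  me <- match_all(text, email)
  mu <- match_all(text, url)
  rule <- c(rep("pat:email", nrow(me)), rep("pat:url", nrow(mu)))
  m <- rbind(me, mu)
  if (nrow(m) == 0L) return(empty_annotations())
  # an email's domain can re-match as url-ish; keep leftmost-longest
  o <- order(m$start, -(m$end - m$start))
  m <- m[o, , drop = FALSE]; rule <- rule[o]
  keep <- rep(TRUE, nrow(m))
  last_end <- -1L
  for (i in seq_len(nrow(m))) {
    if (m$start[i] < last_end) keep[i] <- FALSE else last_end <- m$end[i]
  }
  new_annotations(m$start[keep], m$end[keep], "web_email", rule[keep], text)
}

#' Street-suffix guard
#'
#' A street-suffix word ("Drive", "Street", ...) is only eligible as part of a
#' street address when a number token appears within the preceding window
#' (default 3 word tokens). Blocks phrases like "fitness to drive".
#'
#' @param tokens token data.frame from [tokenize()]
#' @param index row index (into `tokens`) of the street-suffix word
#' @param window how many preceding word tokens to search for a number
#' @return logical
#' @export
street_suffix_guard <- function(tokens, index, window = 3L) {
  widx <- which(tokens$is_word)
  pos <- match(index, widx)
  if (is.na(pos)) return(FALSE)
  back <- widx[seq_len(pos - 1L)]
  back <- utils::tail(back, window)
  any(grepl("^[0-9]+$", tokens$surface[back]))
}

#' Hyphenated-name guard
#'
#' A hyphen-joined token is a hyphenated-surname candidate only when both
#' parts are members of the name lexicons ("Smith-Jones"); otherwise the
#' whole token is protected ("Operative-Smith", "follow-up") and at most a
#' name-listed part remains a candidate on its own.
#'
#' @param token a single hyphenated token
#' @param name_entries character vector of case-folded name-lexicon entries,
#'   or a `LexiconSet` (all `patient_provider_name` entries are used)
#' @return logical
#' @export
hyphen_guard <- function(token, name_entries) {
  if (inherits(name_entries, "LexiconSet")) {
    name_entries <- lexset_entries(name_entries, "patient_provider_name")
  }
  parts <- strsplit(cf(strip_possessive(token)), "-", fixed = TRUE)[[1]]
  length(parts) >= 2L && all(parts %in% name_entries)
}
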