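# Pre-scan text normalization: textual months to numeric dates, and
# structured-field date-of-birth scrubbing. All other dates are preserved —
# visit, procedure and hospitalization dates carry clinical meaning and are
# deliberately left in the text.

month_names <- c(january = 1L, february = 2L, march = 3L, april = 4L,
                 may = 5L, june = 6L, july = 7L, august = 8L,
                 september = 9L, october = 10L, november = 11L,
                 december = 12L)
month_abbrev <- c(jan = 1L, feb = 2L, mar = 3L, apr = 4L, may = 5L, jun = 6L,
                  jul = 7L, aug = 8L, sep = 9L, sept = 9L, oct = 10L,
                  nov = 11L, dec = 12L)

month_number <- function(word) {
  w <- cf(word)
  out <- month_names[w]
  out[is.na(out)] <- month_abbrev[w[is.na(out)]]
  unname(out)
}

month_word_pattern <- function() {
  words <- unique(c(names(month_names), names(month_abbrev)))
  paste0("(?:", paste(words, collapse = "|"), ")")
}

#' Normalize textual month dates to numeric form
#'
#' Rewrites "MonthName D, YYYY", "MonthName D YYYY" and "D MonthName YYYY"
#' mentions (full or 3-letter month names, any case) as zero-padded
#' `mm/dd/yyyy`, e.g. "June 1, 2007" becomes "06/01/2007". Month words are
#' only rewritten inside a full date mention; standalone "May" or "June" flow
#' to the name logic untouched. Numeric dates already in the text are left
#' as-is but reported as mentions. Idempotent.
#'
#' @param text a single string
#' @return list with `text` (rewritten), `mentions` (data.frame of all date
#'   mentions in the *new* text: `start`, `end`, `surface`, `normalized`,
#'   `is_dob`), and `edits` (data.frame mapping original to new spans)
#' @export
normalize_month_dates <- function(text) {
  mw <- month_word_pattern()
  pat1 <- paste0("(?i)\\b(", mw, ")\\.? +([0-9]{1,2})(?:st|nd|rd|th)?(?:,)? +([0-9]{4})\\b")
  pat2 <- paste0("(?i)\\b([0-9]{1,2}) +(", mw, ")\\.?,? +([0-9]{4})\\b")

  hits <- list()
  for (k in 1:2) {
    pat <- if (k == 1) pat1 else pat2
    m <- gregexpr(pat, text, perl = TRUE)[[1]]
    if (m[1] == -1L) next
    start <- as.integer(m) - 1L
    end <- start + attr(m, "match.length")
    surf <- substring(text, start + 1L, end)
    ex <- regmatches(surf, regexec(pat, surf, perl = TRUE))
    for (i in seq_along(surf)) {
      g <- ex[[i]]
      if (k == 1) {
        mon <- month_number(g[2]); day <- as.integer(g[3]); yr <- as.integer(g[4])
      } else {
        day <- as.integer(g[2]); mon <- month_number(g[3]); yr <- as.integer(g[4])
      }
      if (is.na(mon) || !valid_ymd(yr, mon, day)) next
      hits[[length(hits) + 1L]] <- data.frame(
        start = start[i], end = end[i],
        replacement = sprintf("%02d/%02d/%04d", mon, day, yr))
    }
  }
  edits <- data.frame(orig_start = integer(), orig_end = integer(),
                      new_start = integer(), new_end = integer(),
                      replacement = character(), stringsAsFactors = FALSE)
  if (length(hits)) {
    h <- do.call(rbind, hits)
    h <- h[order(h$start), , drop = FALSE]
    # non-overlapping by construction of \b-anchored matches per pattern;
    # guard anyway against pattern-1/pattern-2 double hits
    keep <- rep(TRUE, nrow(h)); last_end <- -1L
    for (i in seq_len(nrow(h))) {
      if (h$start[i] < last_end) keep[i] <- FALSE else last_end <- h$end[i]
    }
    h <- h[keep, , drop = FALSE]
    out <- character(0)
    pos <- 0L   # chars of original consumed
    shift <- 0L
    for (i in seq_len(nrow(h))) {
      out <- c(out, substring(text, pos + 1L, h$start[i]), h$replacement[i])
      new_start <- h$start[i] + shift
      edits <- rbind(edits, data.frame(
        orig_start = h$start[i], orig_end = h$end[i],
        new_start = new_start,
        new_end = new_start + nchar(h$replacement[i]),
        replacement = h$replacement[i], stringsAsFactors = FALSE))
      shift <- shift + nchar(h$replacement[i]) - (h$end[i] - h$start[i])
      pos <- h$end[i]
    }
    out <- c(out, substring(text, pos + 1L, nchar(text)))
    text <- paste(out, collapse = "")
  }
  mentions <- find_date_mentions(text)
  if (nrow(mentions)) {
    parts <- strsplit(gsub("-", "/", mentions$surface), "/", fixed = TRUE)
    mentions$normalized <- vapply(parts, function(p) {
      p <- as.integer(p)
      if (p[1] > 999L) return(sprintf("%02d/%02d/%04d", p[2], p[3], p[1]))
      # slash dates: month-first unless only the day-first reading is valid
      if (valid_ymd(p[3], p[1], p[2])) sprintf("%02d/%02d/%04d", p[1], p[2], p[3])
      else sprintf("%02d/%02d/%04d", p[2], p[1], p[3])
    }, character(1))
    mentions$is_dob <- FALSE
  } else {
    mentions$normalized <- character(); mentions$is_dob <- logical()
  }
  list(text = text, mentions = mentions, edits = edits)
}

# All textual renderings under which a structured DOB is searched for.
# Day-first and month-first readings are both scrubbed (conservative).
dob_renderings <- function(dob) {
  dob <- as.Date(dob)
  if (is.na(dob)) stop("invalid date of birth")
  y <- as.integer(format(dob, "%Y"))
  m <- as.integer(format(dob, "%m"))
  d <- as.integer(format(dob, "%d"))
  unique(c(
    sprintf("%02d/%02d/%04d", m, d, y),
    sprintf("%d/%d/%04d", m, d, y),
    sprintf("%04d-%02d-%02d", y, m, d),
    sprintf("%02d/%02d/%04d", d, m, y),
    sprintf("%d/%d/%04d", d, m, y)
  ))
}

#' Locate date-of-birth mentions using the structured DOB field
#'
#' @param text a single string (month-normalized)
#' @param dob the structured date of birth (`Date` or ISO string)
#' @return annotation data.frame (category `date_of_birth`)
#' @export
find_dob_mentions <- function(text, dob) {
  if (is.null(dob) || (length(dob) == 1L && is.na(dob))) return(empty_annotations())
  rends <- dob_renderings(dob)
  pats <- paste0("(?<![0-9])", regex_escape(rends), "(?![0-9])")
  hits <- lapply(pats, function(p) match_all(text, p))
  m <- do.call(rbind, hits)
  if (nrow(m) == 0L) return(empty_annotations())
  m <- m[!duplicated(m$start), , drop = FALSE]
  m <- m[order(m$start), , drop = FALSE]
  new_annotations(m$start, m$end, "date_of_birth", "ctx:structured_dob", text)
}

#' Scrub the date of birth from text
#'
#' Every rendering of the structured DOB (`mm/dd/yyyy`, `m/d/yyyy`,
#' `yyyy-mm-dd`, and the day-first readings) is replaced by the
#' date-of-birth placeholder tag. All other dates are untouched.
#'
#' @inheritParams find_dob_mentions
#' @param tag replacement placeholder
#' @return the scrubbed text
#' @export
remove_dob <- function(text, dob, tag = "[[date_of_birth]]") {
  ann <- find_dob_mentions(text, dob)
  if (nrow(ann) == 0L) return(text)
  out <- character(0); pos <- 0L
  for (i in seq_len(nrow(ann))) {
    out <- c(out, substring(text, pos + 1L, ann$start[i]), tag)
    pos <- ann$end[i]
  }
  paste(c(out, substring(text, pos + 1L, nchar(text))), collapse = "")
}
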