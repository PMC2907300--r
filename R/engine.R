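# The scan pipeline: line-by-line tokenization, lexicon lookups with context
# heuristics, pattern detectors, clinical-content protections, the
# do-not-remove override, and overlap resolution.

# Pre-computed lookup structure for one compiled LexiconSet, so repeated
# scans do not re-tokenize lexicon entries.
prepare_lexicons <- function(lexset) {
  stopifnot(inherits(lexset, "LexiconSet"))
  tok_entries <- function(entries) {
    lapply(entries, function(e) cf(tokenize(e)$surface))
  }
  loc_group <- function(category, ambiguity, rule) {
    entries <- lexset_entries(lexset, category, ambiguity)
    phr <- tok_entries(entries)
    ord <- order(-lengths(phr))
    list(category = category, ambiguity = ambiguity, rule = rule,
         phrases = phr[ord])
  }
  fac_types <- unlist(unname(lapply(lexset_lexicons(lexset, "facility"),
                                    function(l) l$facility_type %||%
                                      character())))
  list(
    name_unambiguous = lexset_entries(lexset, "patient_provider_name", "unambiguous"),
    name_ambiguous = unique(c(
      lexset_entries(lexset, "patient_provider_name", "ambiguous"),
      lexset_entries(lexset, "patient_provider_name", "popular"))),
    name_all = lexset_entries(lexset, "patient_provider_name"),
    eponyms = lexset_entries(lexset, "eponym"),
    dnr = lexset_entries(lexset, "do_not_remove"),
    locations = list(
      municipality_unambiguous = loc_group("municipality", "unambiguous",
                                           "lex:municipality_unambiguous"),
      municipality_ambiguous = loc_group("municipality", "ambiguous",
                                         "lex:municipality_ambiguous"),
      business_unambiguous = loc_group("business", "unambiguous",
                                       "lex:business_unambiguous"),
      business_ambiguous = loc_group("business", "ambiguous",
                                     "lex:business_ambiguous"),
      facility = loc_group("facility", "unambiguous", "lex:facility")
    ),
    streets = tok_entries(lexset_entries(lexset, "street")),
    facility_types = fac_types
  )
}

# Match tokenized phrases against a token frame; returns data.frame of
# (first_row, last_row) indices into `tokens`. Longest phrase wins at a given
# position; matched tokens are consumed within this call.
match_phrases <- function(tokens, phrases) {
  n <- nrow(tokens)
  out <- list()
  if (n == 0L || !length(phrases)) {
    return(data.frame(first = integer(), last = integer()))
  }
  tok_cf <- cf(tokens$surface)
  used <- rep(FALSE, n)
  for (ph in phrases) {
    L <- length(ph)
    if (L == 0L || L > n) next
    starts <- which(tok_cf == ph[1] & !used)
    for (i in starts) {
      j <- i + L - 1L
      if (j > n) next
      if (any(used[i:j])) next
      if (all(tok_cf[i:j] == ph)) {
        used[i:j] <- TRUE
        out[[length(out) + 1L]] <- c(i, j)
      }
    }
  }
  if (!length(out)) return(data.frame(first = integer(), last = integer()))
  m <- do.call(rbind, out)
  data.frame(first = m[, 1], last = m[, 2])
}

#' Suppress medical eponyms among name candidates
#'
#' Name-category candidates whose surface — with or without a trailing
#' possessive — is a medical eponym (Parkinson's disease, Homan's sign, ...)
#' are dropped: they name a condition, not a person in the record.
#'
#' @param candidates annotation data.frame
#' @param eponyms an eponym `Lexicon`, a `LexiconSet`, or a character vector
#'   of case-folded eponym entries
#' @return filtered annotation data.frame
#' @export
suppress_eponyms <- function(candidates, eponyms) {
  if (inherits(eponyms, "LexiconSet")) {
    eponyms <- lexset_entries(eponyms, "eponym")
  } else if (inherits(eponyms, "Lexicon")) {
    stopifnot(eponyms$category == "eponym")
    eponyms <- cf(eponyms$entries)
  }
  if (nrow(candidates) == 0L || !length(eponyms)) return(candidates)
  is_name <- candidates$category %in% c("patient_name", "provider_name")
  surf <- cf(strip_possessive(candidates$surface))
  drop <- is_name & (surf %in% eponyms | cf(candidates$surface) %in% eponyms)
  candidates[!drop, , drop = FALSE]
}

#' Detect personal names by dictionary lookup and context rules
#'
#' Unambiguous-list tokens are annotated at every occurrence. Ambiguous-list
#' (and popular-list) tokens are annotated only when adjacent to another
#' name-list token or when the immediately preceding or following word is a
#' trigger (title or relationship word). Single letters followed by
#' punctuation are protected, hyphenated tokens pass the hyphenated-name
#' guard, eponyms are suppressed, and adjacent annotated name tokens merge
#' into one span.
#'
#' @param tokens token data.frame for one line (absolute offsets)
#' @param lexicons a `LexiconSet` or the output of the internal preparation
#'   step
#' @param config an [engine_config()]
#' @param text the full source text (for surfaces)
#' @param record optional `Record`; used to label provider names
#' @return annotation data.frame
#' @export
detect_names <- function(tokens, lexicons, config = engine_config(),
                         text = NULL, record = NULL) {
  prep <- if (inherits(lexicons, "LexiconSet")) prepare_lexicons(lexicons) else lexicons
  n <- nrow(tokens)
  if (n == 0L) return(empty_annotations())
  if (is.null(text)) {
    # reconstructible only for surface computation; offsets demand real text
    stop("detect_names requires the source text")
  }
  widx <- which(tokens$is_word)
  if (!length(widx)) return(empty_annotations())
  surf_raw <- tokens$surface[widx]
  surf <- cf(strip_possessive(surf_raw))

  cls <- rep("none", length(widx))
  cls[surf %in% prep$name_ambiguous] <- "amb"
  cls[surf %in% prep$name_unambiguous] <- "unamb"

  # hyphenated tokens: whole-token candidacy only when both parts are names
  sub_spans <- list()
  hy <- grepl("-", surf, fixed = TRUE)
  for (k in which(hy)) {
    parts <- strsplit(surf[k], "-", fixed = TRUE)[[1]]
    inset <- parts %in% prep$name_all
    if (length(parts) >= 2L && all(inset)) {
      cls[k] <- if (any(parts %in% prep$name_unambiguous)) "unamb" else "amb"
    } else {
      cls[k] <- "none"
      named <- which(inset)
      if (length(named) == 1L) {
        # only the name-listed part stays a candidate, on its own
        off <- if (named == 1L) 0L else
          sum(nchar(parts[seq_len(named - 1L)])) + (named - 1L)
        tok_start <- tokens$start[widx[k]]
        part_cls <- if (parts[named] %in% prep$name_unambiguous) "unamb" else "amb"
        sub_spans[[length(sub_spans) + 1L]] <- list(
          start = tok_start + off, end = tok_start + off + nchar(parts[named]),
          cls = part_cls, widx_pos = k)
      }
    }
  }

  # single letters followed by punctuation are protected acronym letters
  single <- nchar(surf_raw) == 1L & grepl("^[A-Za-z]$", surf_raw)
  for (k in which(single & cls != "none")) {
    row <- widx[k]
    follows <- substr(text, tokens$end[row] + 1L, tokens$end[row] + 1L)
    if (is_protected_single_letter(surf_raw[k], follows)) cls[k] <- "none"
  }

  trigger_words <- c(config$trigger_titles, config$trigger_relations)
  neighbor_cf <- function(k, step) {
    k2 <- k + step
    if (k2 < 1L || k2 > length(widx)) return(NA_character_)
    cf(strip_possessive(tokens$surface[widx[k2]]))
  }
  qualified <- cls == "unamb"
  for (k in which(cls == "amb")) {
    prv <- neighbor_cf(k, -1L); nxt <- neighbor_cf(k, 1L)
    ok <- FALSE
    if (config$rule_ambiguous_name_trigger) {
      ok <- ok || (!is.na(prv) && prv %in% trigger_words) ||
        (!is.na(nxt) && nxt %in% trigger_words)
    }
    if (!ok && config$rule_ambiguous_name_adjacency) {
      ok <- (!is.na(prv) && prv %in% prep$name_all && cls[k - 1L] != "none") ||
        (!is.na(nxt) && nxt %in% prep$name_all && cls[k + 1L] != "none")
    }
    qualified[k] <- ok
  }

  anns <- list()
  qk <- which(qualified)
  for (k in qk) {
    row <- widx[k]
    prv <- neighbor_cf(k, -1L)
    nxt <- neighbor_cf(k, 1L)
    is_provider <- (!is.na(prv) && prv %in% c("dr", "prof")) ||
      (!is.null(record) &&
         surf[k] %in% cf(stats::na.omit(c(record$provider_first,
                                          record$provider_last))))
    rule <- if (cls[k] == "unamb") "lex:name_unambiguous" else "ctx:name_context"
    anns[[length(anns) + 1L]] <- data.frame(
      start = tokens$start[row], end = tokens$end[row],
      category = if (is_provider) "provider_name" else "patient_name",
      rule_id = rule, stringsAsFactors = FALSE)
  }
  for (sp in sub_spans) {
    if (sp$cls != "unamb") next  # lone ambiguous sub-part has no usable context
    anns[[length(anns) + 1L]] <- data.frame(
      start = sp$start, end = sp$end, category = "patient_name",
      rule_id = "lex:name_unambiguous", stringsAsFactors = FALSE)
  }
  if (!length(anns)) return(empty_annotations())
  a <- do.call(rbind, anns)
  a <- a[order(a$start), , drop = FALSE]
  out <- new_annotations(a$start, a$end, a$category, a$rule_id, text)
  out <- suppress_eponyms(out, prep$eponyms)
  merge_adjacent_names(out, text)
}

# Merge annotated name tokens separated by whitespace only ("First Last").
merge_adjacent_names <- function(ann, text) {
  if (nrow(ann) <= 1L) return(ann)
  ann <- ann[order(ann$start), , drop = FALSE]
  merged <- list()
  cur <- ann[1, , drop = FALSE]
  for (i in 2:nrow(ann)) {
    gap <- substring(text, cur$end + 1L, ann$start[i])
    namey <- cur$category %in% c("patient_name", "provider_name") &&
      ann$category[i] %in% c("patient_name", "provider_name")
    if (namey && grepl("^\\s+$", gap)) {
      cur$end <- ann$end[i]
      cur$surface <- substring(text, cur$start + 1L, cur$end)
      if (ann$category[i] == "provider_name") cur$category <- "provider_name"
    } else {
      merged[[length(merged) + 1L]] <- cur
      cur <- ann[i, , drop = FALSE]
    }
  }
  merged[[length(merged) + 1L]] <- cur
  do.call(rbind, c(merged, list(make.row.names = FALSE)))
}

#' Detect locations by dictionary lookup with corroborating context
#'
#' Unambiguous municipality, business and facility entries are annotated at
#' every occurrence. Ambiguous entries require corroboration: a location
#' preposition immediately before the mention or a postal code nearby.
#' Street entries are annotated only as part of a full street address —
#' entry followed by a street-suffix word with a house number in the
#' preceding window — so phrases like "fitness to drive" are never touched.
#'
#' @inheritParams detect_names
#' @param postal pre-computed postal-code annotations for the same text
#' @return annotation data.frame
#' @export
detect_locations <- function(tokens, lexicons, config = engine_config(),
                             text = NULL, postal = NULL) {
  prep <- if (inherits(lexicons, "LexiconSet")) prepare_lexicons(lexicons) else lexicons
  if (nrow(tokens) == 0L) return(empty_annotations())
  stopifnot(!is.null(text))
  if (is.null(postal)) postal <- find_postal_codes(text)
  anns <- list()

  for (g in prep$locations) {
    m <- match_phrases(tokens, g$phrases)
    if (nrow(m) == 0L) next
    for (r in seq_len(nrow(m))) {
      s <- tokens$start[m$first[r]]; e <- tokens$end[m$last[r]]
      rule <- g$rule
      if (g$ambiguity == "ambiguous") {
        ok <- FALSE
        if (config$rule_ambiguous_location_preposition) {
          wprev <- utils::tail(which(tokens$is_word & tokens$end <= s), 1)
          ok <- length(wprev) == 1L &&
            cf(tokens$surface[wprev]) %in% config$location_prepositions
          if (ok) rule <- paste0(g$rule, "+preposition")
        }
        if (!ok && config$rule_ambiguous_location_postal && nrow(postal)) {
          near <- abs(postal$start - e) <= config$postal_adjacency_chars |
            abs(s - postal$end) <= config$postal_adjacency_chars
          ok <- any(near)
          if (ok) rule <- paste0(g$rule, "+postal")
        }
        if (!ok) next
      }
      anns[[length(anns) + 1L]] <- data.frame(
        start = s, end = e, category = g$category, rule_id = rule,
        stringsAsFactors = FALSE)
    }
  }

  # street addresses: number (within window) + street entry + suffix
  sm <- match_phrases(tokens, prep$streets)
  if (nrow(sm)) {
    for (r in seq_len(nrow(sm))) {
      last <- sm$last[r]
      nxt <- last + 1L
      if (nxt > nrow(tokens) || !tokens$is_word[nxt]) next
      if (!(cf(tokens$surface[nxt]) %in% config$street_suffixes)) next
      if (!street_suffix_guard(tokens, nxt, config$street_number_window)) next
      widx <- which(tokens$is_word)
      pos <- match(nxt, widx)
      back <- utils::tail(widx[seq_len(pos - 1L)], config$street_number_window)
      numtok <- back[grepl("^[0-9]+$", tokens$surface[back])]
      s <- tokens$start[utils::tail(numtok, 1)]
      anns[[length(anns) + 1L]] <- data.frame(
        start = s, end = tokens$end[nxt], category = "street",
        rule_id = "ctx:street_address", stringsAsFactors = FALSE)
    }
  }

  if (!length(anns)) return(empty_annotations())
  a <- do.call(rbind, anns)
  a <- a[order(a$start), , drop = FALSE]
  new_annotations(a$start, a$end, a$category, a$rule_id, text)
}

#' Apply the do-not-remove override
#'
#' Candidates whose surface (case-folded, possessive-stripped) is on the
#' do-not-remove list, or that sit inside an occurrence of a multi-word
#' do-not-remove phrase, are vetoed. This override outranks every detection
#' decision.
#'
#' @param candidates annotation data.frame
#' @param dnr a `do_not_remove` `Lexicon`, a `LexiconSet`, or a character
#'   vector of case-folded entries
#' @param text the source text (needed for phrase entries)
#' @return filtered annotation data.frame
#' @export
apply_do_not_remove <- function(candidates, dnr, text = NULL) {
  if (inherits(dnr, "LexiconSet")) {
    dnr <- lexset_entries(dnr, "do_not_remove")
  } else if (inherits(dnr, "Lexicon")) {
    stopifnot(dnr$category == "do_not_remove")
    dnr <- cf(dnr$entries)
  }
  if (nrow(candidates) == 0L || !length(dnr)) return(candidates)
  drop <- cf(strip_possessive(candidates$surface)) %in% dnr |
    cf(candidates$surface) %in% dnr
  phrases <- dnr[grepl("\\s", dnr)]
  if (length(phrases) && !is.null(text)) {
    lc_text <- cf(text)
    for (ph in phrases) {
      m <- match_all(lc_text, paste0("(?<![a-z0-9])", regex_escape(ph),
                                     "(?![a-z0-9])"))
      if (nrow(m)) {
        inside <- vapply(seq_len(nrow(candidates)), function(i) {
          any(candidates$start[i] >= m$start & candidates$end[i] <= m$end)
        }, logical(1))
        drop <- drop | inside
      }
    }
  }
  candidates[!drop, , drop = FALSE]
}

#' Resolve overlapping candidate annotations
#'
#' Longer spans win; ties break by category priority (structured number
#' patterns over names over locations), then leftmost. The result is pairwise
#' disjoint and sorted by start.
#'
#' @param candidates annotation data.frame
#' @return disjoint annotation data.frame sorted by start
#' @export
resolve_overlaps <- function(candidates) {
  if (nrow(candidates) <= 1L) return(candidates)
  o <- order(-(candidates$end - candidates$start),
             category_priority(candidates$category), candidates$start)
  cand <- candidates[o, , drop = FALSE]
  keep <- rep(FALSE, nrow(cand))
  taken <- data.frame(start = integer(), end = integer())
  for (i in seq_len(nrow(cand))) {
    if (!span_overlaps_any(cand$start[i], cand$end[i], taken)) {
      keep[i] <- TRUE
      taken <- rbind(taken, cand[i, c("start", "end")])
    }
  }
  out <- cand[keep, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan a record for PHI
#'
#' Orchestrates the full detection pipeline on one record: pattern detectors
#' (postal codes, health card numbers, phones, medical record numbers,
#' web/email), line-by-line name and location detection with context rules
#' and protections, the do-not-remove override, date preservation,
#' date-of-birth detection from the structured field, and overlap resolution.
#' Deterministic: identical inputs yield identical annotation sets. The text
#' is expected to be month-normalized (see [normalize_month_dates()]).
#'
#' @param record a `Record`
#' @param lexicons a compiled `LexiconSet`
#' @param config an [engine_config()]
#' @param prep optional pre-computed lexicon preparation (internal reuse)
#' @return annotation data.frame, pairwise disjoint, sorted by start
#' @export
phi_scan <- function(record, lexicons, config = engine_config(), prep = NULL) {
  stopifnot(inherits(record, "Record"))
  text <- record$text
  if (!nzchar(text)) return(empty_annotations())
  if (is.null(prep)) prep <- prepare_lexicons(lexicons)

  dates <- find_date_mentions(text)
  dob_ann <- find_dob_mentions(text, record$dob)
  postal <- find_postal_codes(text)
  hcn <- find_health_card_numbers(text, dates)
  phone <- find_phone_numbers(text)

  # phone/health-card precedence: context-worded phone wins colliding digits
  if (nrow(phone) && nrow(hcn)) {
    drop_ph <- logical(nrow(phone)); drop_hc <- logical(nrow(hcn))
    for (i in seq_len(nrow(phone))) {
      ov <- which(phone$start[i] < hcn$end & hcn$start < phone$end[i])
      if (length(ov)) {
        if (isTRUE(phone$context[i])) drop_hc[ov] <- TRUE else drop_ph[i] <- TRUE
      }
    }
    phone <- phone[!drop_ph, , drop = FALSE]
    hcn <- hcn[!drop_hc, , drop = FALSE]
  }
  phone$context <- NULL

  claimed <- rbind(dates[, c("start", "end"), drop = FALSE],
                   dob_ann[, c("start", "end"), drop = FALSE],
                   postal[, c("start", "end"), drop = FALSE],
                   hcn[, c("start", "end"), drop = FALSE],
                   phone[, c("start", "end"), drop = FALSE])
  mrn <- find_medical_record_numbers(text, claimed)
  web <- find_web_email(text)

  # line-by-line lexicon scan; no annotation spans a newline
  tokens <- tokenize(text)
  nl <- c(-1L, which(strsplit(text, "", fixed = TRUE)[[1]] == "\n") - 1L)
  line_of <- findInterval(tokens$start, nl)
  names_ann <- list(); loc_ann <- list()
  for (ln in unique(line_of)) {
    tl <- tokens[line_of == ln, , drop = FALSE]
    names_ann[[length(names_ann) + 1L]] <-
      detect_names(tl, prep, config, text, record)
    loc_ann[[length(loc_ann) + 1L]] <-
      detect_locations(tl, prep, config, text, postal)
  }

  cands <- bind_annotations(postal, hcn, phone, mrn, web,
                            do.call(bind_annotations, names_ann),
                            do.call(bind_annotations, loc_ann))
  cands <- apply_do_not_remove(cands, prep$dnr, text)
  # date preservation: nothing but the DOB rule may touch a date mention
  if (nrow(cands) && nrow(dates)) {
    cands <- cands[!span_overlaps_any(cands$start, cands$end, dates) |
                     cands$category == "date_of_birth", , drop = FALSE]
  }
  out <- resolve_overlaps(bind_annotations(cands, dob_ann))
  check_annotations(out, text)
  out
}
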