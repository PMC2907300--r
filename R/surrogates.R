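# Surrogate (pseudonym) replacement: the clinic-side initial name removal and
# the final category-consistent substitution. Surrogates are drawn from the
# detection lexicons so that any PHI the scan missed hides in plain sight
# among the pseudonyms.

# Draw surrogate pools out of a compiled LexiconSet.
surrogate_pools <- function(lexset) {
  first_f <- lexset$lexicons$name_first_female$entries %||% character()
  first_m <- lexset$lexicons$name_first_male$entries %||% character()
  una <- lexset$lexicons$name_unambiguous$entries %||% character()
  last <- setdiff(una, c(first_f, first_m))
  if (!length(last)) last <- una
  fac <- lexset_lexicons(lexset, "facility")
  fac_entries <- unlist(lapply(fac, `[[`, "entries"), use.names = FALSE)
  fac_types <- unlist(unname(lapply(fac, function(l) l$facility_type %||%
                                      stats::setNames(rep("other", length(l$entries)),
                                                      cf(l$entries)))))
  if (is.null(fac_types)) fac_types <- character()
  display_entries <- function(category, ambiguity) {
    unlist(lapply(lexset_lexicons(lexset, category, ambiguity),
                  `[[`, "entries"), use.names = FALSE)
  }
  list(
    first_female = if (length(first_f)) first_f else una,
    first_male = if (length(first_m)) first_m else una,
    first_any = unique(c(first_f, first_m, if (!length(c(first_f, first_m))) una)),
    last = last,
    facility = fac_entries,
    facility_types = fac_types,
    street = lexset$lexicons$street$entries %||% character(),
    municipality = display_entries("municipality", "unambiguous"),
    business = display_entries("business", "unambiguous")
  )
}

draw <- function(pool, avoid = NULL) {
  stopifnot(length(pool) > 0L)
  p <- if (!is.null(avoid)) setdiff(pool, pool[cf(pool) %in% cf(avoid)]) else pool
  if (!length(p)) p <- pool
  p[sample.int(length(p), 1L)]
}

random_digits <- function(n) paste(sample(0:9, n, replace = TRUE), collapse = "")

# Letters that can never be mistaken for protected clinical nomenclature
# (excludes C/T/L/S spinal letters and the G/P/A obstetric letters).
postal_safe_letters <- c("B", "E", "H", "J", "K", "M", "N", "R", "V", "X", "Y")

random_postal <- function(with_space) {
  l <- sample(postal_safe_letters, 3L, replace = TRUE)
  d <- sample(0:9, 3L, replace = TRUE)
  paste0(l[1], d[1], l[2], if (with_space) " " else "", d[2], l[3], d[3])
}

# Replace every digit with a random digit and every letter with a random
# uppercase letter, preserving the grouping shape.
shape_preserving_number <- function(surface) {
  chars <- strsplit(surface, "", fixed = TRUE)[[1]]
  digs <- grepl("[0-9]", chars)
  lets <- grepl("[A-Za-z]", chars)
  chars[digs] <- as.character(sample(0:9, sum(digs), replace = TRUE))
  chars[lets] <- sample(LETTERS, sum(lets), replace = TRUE)
  paste(chars, collapse = "")
}

random_word <- function(nchars) {
  paste(sample(letters, max(2L, nchars), replace = TRUE), collapse = "")
}

random_email <- function() {
  paste0(random_word(6), ".", random_word(5), "@", random_word(7), ".com")
}

#' Clinic-side initial name removal
#'
#' Replaces every occurrence of the structured patient and provider names in
#' the free text (full name, first alone, last alone, case-insensitive) with
#' a seeded, gender-matched fake first and last name, used consistently
#' within the record. The structured name fields are updated to the fake
#' name; the original-to-fake mapping is attached as the `name_map`
#' attribute.
#'
#' @param record a `Record`
#' @param pools a compiled `LexiconSet` (fake names are drawn from its
#'   unambiguous name pools)
#' @param seed integer seed
#' @return the `Record` with substituted text; original names never occur in
#'   the output text
#' @export
initial_name_removal <- function(record, pools, seed = 1L) {
  if (inherits(pools, "LexiconSet")) pools <- surrogate_pools(pools)
  withr::with_seed(seed, {
    map <- list()
    swap_person <- function(text, first, last, gender) {
      if ((is.na(first) || !nzchar(first)) && (is.na(last) || !nzchar(last))) {
        warning("empty structured name; skipping initial name removal")
        return(list(text = text, fake = c(NA_character_, NA_character_)))
      }
      fpool <- switch(gender, M = pools$first_male, F = pools$first_female,
                      pools$first_any)
      fake_first <- draw(fpool, avoid = c(first, last))
      fake_last <- draw(pools$last, avoid = c(first, last, fake_first))
      for (piece in list(c(first, fake_first), c(last, fake_last))) {
        if (is.na(piece[1]) || !nzchar(piece[1])) next
        pat <- paste0("(?i)(?<![A-Za-z0-9])", regex_escape(piece[1]),
                      "(?![A-Za-z0-9])")
        text <- gsub(pat, piece[2], text, perl = TRUE)
      }
      list(text = text, fake = c(fake_first, fake_last))
    }
    text <- record$text
    p <- swap_person(text, record$patient_first, record$patient_last,
                     record$gender)
    text <- p$text
    q <- swap_person(text, record$provider_first, record$provider_last, "U")
    text <- q$text
    out <- record
    out$text <- text
    map$patient <- c(original_first = record$patient_first,
                     original_last = record$patient_last,
                     fake_first = p$fake[1], fake_last = p$fake[2])
    map$provider <- c(original_first = record$provider_first,
                      original_last = record$provider_last,
                      fake_first = q$fake[1], fake_last = q$fake[2])
    if (!is.na(p$fake[1])) {
      out$patient_first <- p$fake[1]; out$patient_last <- p$fake[2]
    }
    if (!is.na(q$fake[1])) {
      out$provider_first <- q$fake[1]; out$provider_last <- q$fake[2]
    }
    attr(out, "name_map") <- map
    out
  })
}

#' Replace detected PHI with surrogates or category tags
#'
#' In `tag` mode each span becomes `[[category]]`. In `pseudonym` mode each
#' span becomes a seeded surrogate of the same category: names are
#' gender-matched when the record's gender is known, facilities keep their
#' facility type, identifier numbers keep their digit-grouping shape, and
#' postal codes keep their spacing. Identical surfaces within a record map to
#' identical surrogates. Characters outside annotated spans are byte-
#' identical to the input.
#'
#' @param record a `Record` (or a plain string)
#' @param annotations disjoint, in-bounds annotation data.frame
#' @param surrogate_pools a compiled `LexiconSet` (pools are drawn from it)
#' @param seed integer seed
#' @param mode `"pseudonym"` or `"tag"`
#' @return a `DeidResult`: list with `text`, `annotations` (the input),
#'   `surrogate_map` (data.frame original/category/surrogate), and `edits`
#'   (data.frame mapping original to new offsets)
#' @export
replace_phi <- function(record, annotations, surrogate_pools = NULL,
                        seed = 1L, mode = c("pseudonym", "tag")) {
  mode <- match.arg(mode)
  text <- if (inherits(record, "Record")) record$text else record
  gender <- if (inherits(record, "Record")) record$gender else "U"
  ann <- annotations
  if (nrow(ann)) {
    check_annotations(ann, text)
    o <- order(ann$start)
    ann <- ann[o, , drop = FALSE]
    if (any(ann$start[-1] < ann$end[-nrow(ann)])) {
      stop("annotations must be pairwise disjoint")
    }
  }
  pools <- if (inherits(surrogate_pools, "LexiconSet")) {
    surrogate_pools(surrogate_pools)
  } else surrogate_pools

  make_surrogate <- function(surface, category) {
    if (mode == "tag") return(paste0("[[", category, "]]"))
    poss <- grepl("['’][sS]$", surface, perl = TRUE)
    base <- strip_possessive(surface)
    out <- switch(
      category,
      patient_name = ,
      provider_name = {
        k <- sum(tokenize(base)$is_word)
        fpool <- switch(gender, M = pools$first_male, F = pools$first_female,
                        pools$first_any)
        parts <- c(draw(fpool, avoid = base),
                   if (k > 1L) replicate(k - 1L, draw(pools$last, avoid = base)))
        paste(parts[seq_len(max(1L, k))], collapse = " ")
      },
      facility = {
        tp <- pools$facility_types[cf(base)] %||% NA_character_
        pool <- if (!is.na(tp)) {
          pools$facility[pools$facility_types[cf(pools$facility)] == tp]
        } else pools$facility
        pool <- pool[!is.na(pool)]
        draw(if (length(pool)) pool else pools$facility, avoid = base)
      },
      street = {
        num <- regmatches(base, regexpr("^[0-9]+", base))
        sfx <- regmatches(base, regexpr("[A-Za-z]+$", base))
        nm <- draw(pools$street, avoid = base)
        paste(c(if (length(num)) random_digits(nchar(num)), nm,
                if (length(sfx)) sfx), collapse = " ")
      },
      municipality = draw(pools$municipality, avoid = base),
      business = draw(pools$business, avoid = base),
      postal_code = random_postal(grepl(" ", base, fixed = TRUE)),
      health_card_number = ,
      medical_record_number = ,
      phone_number = shape_preserving_number(base),
      web_email = random_email(),
      date_of_birth = {
        d <- as.Date("1930-01-01") + sample.int(25000L, 1L)
        s <- format(d, "%m/%d/%Y")
        while (identical(s, base)) {
          d <- as.Date("1930-01-01") + sample.int(25000L, 1L)
          s <- format(d, "%m/%d/%Y")
        }
        s
      },
      paste0("[[", category, "]]")
    )
    if (poss) out <- paste0(out, "'s")
    out
  }

  withr::with_seed(seed, {
    map <- new.env(parent = emptyenv())
    pieces <- character(0)
    edits <- data.frame(orig_start = integer(), orig_end = integer(),
                        new_start = integer(), new_end = integer(),
                        surrogate = character(), stringsAsFactors = FALSE)
    pos <- 0L; shift <- 0L
    for (i in seq_len(nrow(ann))) {
      key <- paste0(ann$category[i], "\r", cf(ann$surface[i]))
      if (is.null(map[[key]])) map[[key]] <- make_surrogate(ann$surface[i],
                                                            ann$category[i])
      sur <- map[[key]]
      pieces <- c(pieces, substring(text, pos + 1L, ann$start[i]), sur)
      new_start <- ann$start[i] + shift
      edits <- rbind(edits, data.frame(
        orig_start = ann$start[i], orig_end = ann$end[i],
        new_start = new_start, new_end = new_start + nchar(sur),
        surrogate = sur, stringsAsFactors = FALSE))
      shift <- shift + nchar(sur) - (ann$end[i] - ann$start[i])
      pos <- ann$end[i]
    }
    new_text <- paste(c(pieces, substring(text, pos + 1L, nchar(text))),
                      collapse = "")
    keys <- ls(map)
    smap <- data.frame(
      original = sub("^[^\r]*\r", "", keys),
      category = sub("\r.*$", "", keys),
      surrogate = vapply(keys, function(k) map[[k]], character(1)),
      stringsAsFactors = FALSE, row.names = NULL
    )
    structure(list(text = new_text, annotations = ann, surrogate_map = smap,
                   edits = edits, mode = mode, seed = seed),
              class = "DeidResult")
  })
}

#' @export
print.DeidResult <- function(x, ...) {
  cat(sprintf("<DeidResult: %d spans replaced (%s mode), %d chars>\n",
              nrow(x$annotations), x$mode, nchar(x$text)))
  invisible(x)
}
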