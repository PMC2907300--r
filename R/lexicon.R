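# Lexicon (gazetteer) construction and compilation.
#
# A Lexicon is a named, categorized set of surface forms with an ambiguity
# class. Detection lexicons drive dictionary lookup in the scan engine;
# protective lexicons (eponyms, common words, do-not-remove) veto detections.
# Compilation applies the precedence and filtering rules that keep the sets
# consistent: cross-list splitting into ambiguous/unambiguous, common-word
# filtering, nickname merging, and popular-name precedence.

lexicon_categories <- function() {
  c("patient_provider_name", "street", "municipality", "facility",
    "business", "eponym", "nickname", "common_word", "do_not_remove")
}

ambiguity_classes <- function() c("ambiguous", "unambiguous", "popular", "protective")

#' Construct a Lexicon
#'
#' Entries are whitespace-trimmed and de-duplicated after case folding (the
#' first-seen original-case form is kept as the display form).
#'
#' @param name short identifier
#' @param category one of [lexicon_categories()]
#' @param ambiguity one of `ambiguous`, `unambiguous`, `popular`, `protective`
#' @param entries character vector of surface forms
#' @param facility_type optional named character vector mapping case-folded
#'   facility entries to a subtype (hospital, radiology_clinic,
#'   medical_laboratory, physiotherapy_clinic, other); only for facilities
#' @return object of class `Lexicon`
#' @export
new_lexicon <- function(name, category, ambiguity, entries = character(),
                        facility_type = NULL) {
  category <- match.arg(category, lexicon_categories())
  ambiguity <- match.arg(ambiguity, ambiguity_classes())
  if (ambiguity == "protective" &&
      !category %in% c("eponym", "common_word", "do_not_remove", "nickname")) {
    stop("protective ambiguity is reserved for eponym/common_word/do_not_remove/nickname lexicons")
  }
  entries <- trimws(as.character(entries))
  entries <- entries[nzchar(entries)]
  entries <- entries[!duplicated(cf(entries))]
  structure(list(name = name, category = category, ambiguity = ambiguity,
                 entries = entries, facility_type = facility_type),
            class = "Lexicon")
}

#' @export
print.Lexicon <- function(x, ...) {
  cat(sprintf("<Lexicon %s: %s/%s, %d entries>\n",
              x$name, x$category, x$ambiguity, length(x$entries)))
  invisible(x)
}

#' Load a lexicon from a one-entry-per-line text file
#'
#' Blank lines and lines starting with `#` are skipped; entries are trimmed
#' and de-duplicated case-insensitively.
#'
#' @inheritParams new_lexicon
#' @param path path to a UTF-8 text file
#' @return a `Lexicon`
#' @export
load_lexicon <- function(path, category, ambiguity,
                         name = tools::file_path_sans_ext(basename(path))) {
  if (!file.exists(path)) stop("lexicon file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  lex <- new_lexicon(name, category, ambiguity, lines)
  if (length(lex$entries) == 0L) {
    warning("lexicon '", name, "' loaded from ", path, " is empty")
  }
  lex
}

#' Split a lexicon into ambiguous and unambiguous parts
#'
#' Entries that also occur (case-folded) on any of the `others` lexicons are
#' ambiguous — they require corroborating context before the engine will
#' annotate them. All remaining entries are unambiguous. The two outputs
#' partition the input.
#'
#' @param target a `Lexicon`
#' @param others list of `Lexicon` objects to cross-reference against
#' @return list with elements `ambiguous` and `unambiguous`
#' @export
split_ambiguous <- function(target, others) {
  other_entries <- unique(cf(unlist(lapply(others, function(l) l$entries),
                                    use.names = FALSE)))
  hit <- cf(target$entries) %in% other_entries
  list(
    ambiguous = new_lexicon(paste0(target$name, "_ambiguous"),
                            target$category, "ambiguous",
                            target$entries[hit],
                            facility_type = target$facility_type),
    unambiguous = new_lexicon(paste0(target$name, "_unambiguous"),
                              target$category, "unambiguous",
                              target$entries[!hit],
                              facility_type = target$facility_type)
  )
}

#' Remove common English words from a lexicon
#'
#' Entries that are also commonly used English words are removed so clinical
#' phrases are not destroyed by dictionary lookup. The unambiguous names list
#' is screened against a shorter list of only the most common words (realized
#' as the first `short_n` entries of the full, frequency-ordered list); all
#' other lists use the full list.
#'
#' @param target a `Lexicon`
#' @param common a `common_word` lexicon, frequency-ordered
#' @param mode `"full"` or `"short"`
#' @param short_n number of top entries forming the short list
#' @return filtered `Lexicon`
#' @export
filter_common_words <- function(target, common, mode = c("full", "short"),
                                short_n = 1000L) {
  mode <- match.arg(mode)
  stopifnot(common$category == "common_word")
  words <- common$entries
  if (mode == "short") words <- utils::head(words, short_n)
  keep <- !(cf(target$entries) %in% cf(words))
  out <- target
  out$entries <- target$entries[keep]
  out
}

#' Apply popular-name precedence across the three name lists
#'
#' Popular names are deleted from the unambiguous and ambiguous lists, and
#' names on both the unambiguous and ambiguous lists are deleted from the
#' ambiguous list.
#'
#' @param popular,unambiguous,ambiguous name lexicons
#' @return list with adjusted `popular`, `unambiguous`, `ambiguous`
#' @export
apply_name_precedence <- function(popular, unambiguous, ambiguous) {
  pop <- cf(popular$entries)
  unambiguous$entries <- unambiguous$entries[!(cf(unambiguous$entries) %in% pop)]
  ambiguous$entries <- ambiguous$entries[!(cf(ambiguous$entries) %in% pop)]
  ambiguous$entries <-
    ambiguous$entries[!(cf(ambiguous$entries) %in% cf(unambiguous$entries))]
  list(popular = popular, unambiguous = unambiguous, ambiguous = ambiguous)
}

#' Merge a nickname list into the ambiguous names list
#'
#' @param ambiguous_names ambiguous name lexicon
#' @param nicknames nickname lexicon
#' @return merged ambiguous `Lexicon`
#' @export
merge_nicknames <- function(ambiguous_names, nicknames) {
  stopifnot(nicknames$category == "nickname")
  new_lexicon(ambiguous_names$name, ambiguous_names$category, "ambiguous",
              c(ambiguous_names$entries, nicknames$entries))
}

#' Construct a LexiconSet
#'
#' @param lexicons named list of `Lexicon` objects
#' @param provenance free-text description of each list's source
#' @return object of class `LexiconSet` with a content checksum
#' @export
new_lexicon_set <- function(lexicons, provenance = character()) {
  stopifnot(is.list(lexicons), all(vapply(lexicons, inherits, logical(1), "Lexicon")))
  if (is.null(names(lexicons)) || any(!nzchar(names(lexicons)))) {
    names(lexicons) <- vapply(lexicons, `[[`, character(1), "name")
  }
  lines <- unlist(lapply(names(lexicons), function(nm) {
    paste(nm, cf(lexicons[[nm]]$entries), sep = "\t")
  }), use.names = FALSE)
  structure(list(lexicons = lexicons, provenance = provenance,
                 checksum = content_checksum(lines)),
            class = "LexiconSet")
}

#' @export
print.LexiconSet <- function(x, ...) {
  cat(sprintf("<LexiconSet: %d lexicons, checksum %s>\n",
              length(x$lexicons), x$checksum))
  for (l in x$lexicons) print(l)
  invisible(x)
}

#' Pull case-folded entries from a LexiconSet by category/ambiguity
#'
#' @param set a `LexiconSet`
#' @param category lexicon category
#' @param ambiguity optional ambiguity filter
#' @return character vector of case-folded entries (may be empty)
#' @export
lexset_entries <- function(set, category, ambiguity = NULL) {
  sel <- Filter(function(l) {
    l$category == category && (is.null(ambiguity) || l$ambiguity == ambiguity)
  }, set$lexicons)
  unique(cf(unlist(lapply(sel, `[[`, "entries"), use.names = FALSE)))
}

# Select the Lexicon objects themselves.
lexset_lexicons <- function(set, category, ambiguity = NULL) {
  Filter(function(l) {
    l$category == category && (is.null(ambiguity) || l$ambiguity == ambiguity)
  }, set$lexicons)
}

#' Validate LexiconSet invariants
#'
#' Checks that (i) no entry sits on both the unambiguous and ambiguous lists
#' of one category, (ii) no popular name appears on any other name list, and
#' (iii) no do-not-remove entry appears in any detection lexicon.
#'
#' @param set a `LexiconSet`
#' @return `TRUE` invisibly; stops with a message on violation
#' @export
validate_lexicon_set <- function(set) {
  detect_cats <- c("patient_provider_name", "street", "municipality",
                   "facility", "business")
  for (cat in detect_cats) {
    amb <- lexset_entries(set, cat, "ambiguous")
    una <- lexset_entries(set, cat, "unambiguous")
    both <- intersect(amb, una)
    if (length(both)) {
      stop("entries on both ambiguous and unambiguous ", cat, " lists: ",
           paste(utils::head(both, 5), collapse = ", "))
    }
  }
  pop <- lexset_entries(set, "patient_provider_name", "popular")
  other_names <- c(lexset_entries(set, "patient_provider_name", "ambiguous"),
                   lexset_entries(set, "patient_provider_name", "unambiguous"))
  leak <- intersect(pop, other_names)
  if (length(leak)) {
    stop("popular names leaked into other name lists: ",
         paste(utils::head(leak, 5), collapse = ", "))
  }
  dnr <- lexset_entries(set, "do_not_remove")
  detect_all <- unique(unlist(lapply(detect_cats, lexset_entries, set = set)))
  veto <- intersect(dnr, detect_all)
  if (length(veto)) {
    stop("do-not-remove entries present in detection lexicons: ",
         paste(utils::head(veto, 5), collapse = ", "))
  }
  invisible(TRUE)
}

# --- compilation ------------------------------------------------------------

facility_types <- function() {
  c("hospital", "radiology_clinic", "medical_laboratory",
    "physiotherapy_clinic", "other")
}

# Business entries that are pharmacies or insurance companies are dropped;
# radiology clinics, medical laboratories and physiotherapy clinics are moved
# to the healthcare facilities list so they can be surrogate-replaced by a
# facility of the same type.
reclassify_businesses <- function(businesses, facilities) {
  e <- businesses$entries
  lc <- cf(e)
  drop <- grepl("pharmac|insurance", lc)
  move_type <- rep(NA_character_, length(e))
  move_type[grepl("radiolog|x-ray|imaging", lc)] <- "radiology_clinic"
  move_type[grepl("laborator", lc)] <- "medical_laboratory"
  move_type[grepl("physiotherap", lc)] <- "physiotherapy_clinic"
  move <- !is.na(move_type) & !drop
  ft <- facilities$facility_type %||% stats::setNames(
    rep("other", length(facilities$entries)), cf(facilities$entries))
  if (any(move)) {
    ft <- c(ft, stats::setNames(move_type[move], lc[move]))
  }
  facilities <- new_lexicon(facilities$name, "facility", facilities$ambiguity,
                            c(facilities$entries, e[move]),
                            facility_type = ft)
  businesses$entries <- e[!(drop | move)]
  list(businesses = businesses, facilities = facilities)
}

#' Compile a LexiconSet from a manifest
#'
#' Executes the full compilation recipe: load each source list, apply the
#' business reclassification moves (pharmacies/insurance dropped;
#' radiology/laboratory/physiotherapy entries moved to facilities), split
#' municipalities and businesses into ambiguous/unambiguous by
#' cross-referencing all other lists, filter common words (short list for the
#' unambiguous names), merge nicknames and provider names into the ambiguous
#' names, apply popular-name precedence, and finally strip exact
#' do-not-remove entries from every detection lexicon.
#'
#' @param manifest path to a YAML manifest, or an equivalent list. Keys:
#'   `lists` (role -> file path) with roles `name_unambiguous`,
#'   `name_first_female`, `name_first_male`, `name_ambiguous`, `name_popular`,
#'   `nickname`, `provider_name`, `street`, `municipality`, `business`,
#'   `eponym`, `common_word`, `do_not_remove`; `facilities` (type -> path);
#'   `options$short_common_n`.
#' @param base_dir directory against which relative paths are resolved
#' @return compiled `LexiconSet` passing [validate_lexicon_set()]
#' @export
compile_lexicon_set <- function(manifest, base_dir = ".") {
  if (is.character(manifest)) {
    base_dir <- dirname(manifest)
    manifest <- yaml::read_yaml(manifest)
  }
  lists <- manifest$lists
  resolve <- function(p) if (file.exists(p)) p else file.path(base_dir, p)
  need <- function(role) {
    p <- lists[[role]]
    if (is.null(p)) stop("manifest is missing required list role: ", role)
    p <- resolve(p)
    if (!file.exists(p)) stop("manifest references a missing file: ", p,
                              " (role ", role, ")")
    p
  }
  opt <- manifest$options %||% list()
  short_n <- as.integer(opt$short_common_n %||% 1000L)

  lx <- list(
    name_unambiguous = load_lexicon(need("name_unambiguous"),
                                    "patient_provider_name", "unambiguous"),
    name_ambiguous = load_lexicon(need("name_ambiguous"),
                                  "patient_provider_name", "ambiguous"),
    name_popular = load_lexicon(need("name_popular"),
                                "patient_provider_name", "popular"),
    nickname = load_lexicon(need("nickname"), "nickname", "protective"),
    street = load_lexicon(need("street"), "street", "unambiguous"),
    municipality = load_lexicon(need("municipality"), "municipality", "unambiguous"),
    business = load_lexicon(need("business"), "business", "unambiguous"),
    eponym = load_lexicon(need("eponym"), "eponym", "protective"),
    common_word = load_lexicon(need("common_word"), "common_word", "protective"),
    do_not_remove = load_lexicon(need("do_not_remove"), "do_not_remove", "protective")
  )
  # Optional gender-specific surrogate pools; merged into the unambiguous list.
  pools <- list()
  for (role in c("name_first_female", "name_first_male")) {
    if (!is.null(lists[[role]])) {
      pools[[role]] <- load_lexicon(need(role), "patient_provider_name",
                                    "unambiguous", name = role)
    }
  }
  if (!is.null(lists$provider_name)) {
    provider <- load_lexicon(need("provider_name"), "patient_provider_name",
                             "ambiguous", name = "provider_name")
  } else provider <- NULL

  fac_entries <- character(); fac_types <- character()
  for (tp in names(manifest$facilities %||% list())) {
    p <- resolve(manifest$facilities[[tp]])
    if (!file.exists(p)) stop("manifest references a missing file: ", p,
                              " (facility type ", tp, ")")
    l <- load_lexicon(p, "facility", "unambiguous")
    fac_entries <- c(fac_entries, l$entries)
    fac_types <- c(fac_types, stats::setNames(rep(tp, length(l$entries)),
                                              cf(l$entries)))
  }
  facilities <- new_lexicon("facility", "facility", "unambiguous",
                            fac_entries, facility_type = fac_types)

  # 1. reclassification moves
  moved <- reclassify_businesses(lx$business, facilities)
  lx$business <- moved$businesses
  facilities <- moved$facilities

  # 2. cross-list ambiguity split for municipalities and businesses
  name_lex <- c(list(lx$name_unambiguous, lx$name_ambiguous, lx$name_popular,
                     lx$nickname), pools, list(provider))
  name_lex <- Filter(Negate(is.null), name_lex)
  muni_split <- split_ambiguous(lx$municipality,
                                c(name_lex, list(lx$street, facilities, lx$business)))
  busi_split <- split_ambiguous(lx$business,
                                c(name_lex, list(lx$street, facilities,
                                                 lx$municipality)))

  # 3. common-word filtering (short list for unambiguous names only)
  common <- lx$common_word
  filt <- function(l, mode = "full") filter_common_words(l, common, mode, short_n)
  lx$name_unambiguous <- filt(lx$name_unambiguous, "short")
  pools <- lapply(pools, filt, mode = "short")
  lx$name_ambiguous <- filt(lx$name_ambiguous)
  lx$name_popular <- filt(lx$name_popular)
  if (!is.null(provider)) provider <- filt(provider)
  lx$street <- filt(lx$street)
  muni_split <- lapply(muni_split, filt)
  busi_split <- lapply(busi_split, filt)
  facilities <- filt(facilities)

  # 4. nickname + provider merge into ambiguous names
  amb <- merge_nicknames(lx$name_ambiguous, lx$nickname)
  if (!is.null(provider)) {
    amb <- new_lexicon(amb$name, "patient_provider_name", "ambiguous",
                       c(amb$entries, provider$entries))
  }

  # 5. popular precedence, then unambiguous > ambiguous
  una_all <- new_lexicon("name_unambiguous", "patient_provider_name",
                         "unambiguous",
                         c(lx$name_unambiguous$entries,
                           unlist(lapply(pools, `[[`, "entries"), use.names = FALSE)))
  prec <- apply_name_precedence(lx$name_popular, una_all, amb)

  # Keep gender pools consistent with the precedence-adjusted unambiguous set.
  keep_cf <- cf(prec$unambiguous$entries)
  pools <- lapply(pools, function(p) {
    p$entries <- p$entries[cf(p$entries) %in% keep_cf]
    p
  })

  out <- c(list(
    name_unambiguous = prec$unambiguous,
    name_ambiguous = prec$ambiguous,
    name_popular = prec$popular,
    street = lx$street,
    municipality_ambiguous = muni_split$ambiguous,
    municipality_unambiguous = muni_split$unambiguous,
    business_ambiguous = busi_split$ambiguous,
    business_unambiguous = busi_split$unambiguous,
    facility = facilities,
    eponym = lx$eponym,
    common_word = common,
    do_not_remove = lx$do_not_remove
  ), pools)

  # 6. do-not-remove entries never sit on a detection lexicon
  dnr <- cf(lx$do_not_remove$entries)
  detect <- c("patient_provider_name", "street", "municipality", "facility",
              "business")
  out <- lapply(out, function(l) {
    if (l$category %in% detect) l$entries <- l$entries[!(cf(l$entries) %in% dnr)]
    l
  })

  prov <- vapply(names(manifest$lists %||% list()), function(r)
    paste0(r, ": ", manifest$lists[[r]]), character(1))
  set <- new_lexicon_set(out, provenance = prov)
  validate_lexicon_set(set)
  set
}

#' Serialize a LexiconSet to a directory
#'
#' One text file per lexicon plus a JSON manifest with per-file checksums.
#'
#' @param set a `LexiconSet`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_lexicon_set <- function(set, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(checksum = set$checksum, provenance = set$provenance,
               lexicons = list())
  for (nm in names(set$lexicons)) {
    l <- set$lexicons[[nm]]
    f <- file.path(dir, paste0(nm, ".txt"))
    writeLines(l$entries, f, useBytes = TRUE)
    meta$lexicons[[nm]] <- list(
      file = basename(f), category = l$category, ambiguity = l$ambiguity,
      checksum = content_checksum(cf(l$entries)),
      facility_type = as.list(l$facility_type %||% character())
    )
  }
  jsonlite::write_json(meta, file.path(dir, "lexicons.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read a serialized LexiconSet
#'
#' @param dir directory written by [write_lexicon_set()]
#' @return a `LexiconSet`
#' @export
read_lexicon_set <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "lexicons.json"))
  lexicons <- lapply(names(meta$lexicons), function(nm) {
    m <- meta$lexicons[[nm]]
    ft <- unlist(m$facility_type)
    if (!length(ft)) ft <- NULL
    lex <- load_lexicon(file.path(dir, m$file), m$category, m$ambiguity, name = nm)
    lex$facility_type <- ft
    lex
  })
  names(lexicons) <- names(meta$lexicons)
  new_lexicon_set(lexicons, provenance = unlist(meta$provenance))
}
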