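# Seeded generator of synthetic lexicons and synthetic primary-care EMR
# records with gold PHI annotations and decoys. Stands in for private source
# lists (provincial registries, medical directories) and private clinical
# corpora: the file shapes and the detection-relevant structure are emulated,
# not any real person's data.

# Invented-word machinery: gazetteer entries are built from syllables so they
# cannot collide with the clinical filler vocabulary except where a collision
# is planted on purpose (and logged).
syn_syllables <- c("bar", "ven", "dor", "mal", "tek", "rin", "sol", "gar",
                   "nim", "pel", "tra", "vos", "kel", "mur", "zan", "fir",
                   "lod", "bex", "tun", "hav", "ryl", "ost", "dra", "wex",
                   "yor", "quin", "fen", "gol", "sab", "tor")

syn_filler_sentences <- c(
  "Patient doing well overall.", "Blood pressure well controlled.",
  "Discussed diet and exercise.", "Medications reviewed and renewed.",
  "No new concerns today.", "Sleep has improved.", "Reports mild fatigue.",
  "Bloodwork reviewed with patient.", "Symptoms have settled.",
  "Will continue current management.", "No chest pain or dyspnea.",
  "Denies fever or weight loss.")

# Frequency-ordered common-English-word list bundled with the generator; the
# short most-common list is its top slice.
syn_common_words <- c(
  "the", "and", "of", "to", "a", "in", "is", "was", "for", "with", "on",
  "as", "at", "be", "this", "have", "from", "or", "by", "not", "but",
  "all", "are", "his", "her", "she", "he", "had", "has", "will", "one",
  "no", "new", "more", "when", "who", "out", "up", "about", "into",
  "may", "june", "park", "drive", "white", "young", "price", "stone",
  "bill", "summer", "winter", "hill", "brown", "green", "lake", "wood",
  "field", "bridge", "mill", "king", "forest", "rose", "day", "home",
  "visit", "note", "pain", "left", "right", "well", "normal", "clear",
  "stable", "good", "follow", "plan", "today", "seen", "denies",
  "reports", "exam", "chest", "heart", "sounds", "lungs", "daily",
  "twice", "review", "continue", "start", "stop", "increase", "decrease",
  "refer", "discussed", "advised", "patient", "history", "family")

syn_do_not_remove <- c(
  "assessment", "emergency", "st", "soap", "ecg", "mri", "ct",
  "canada", "france", "mexico", "italy", "germany", "china", "india",
  "shoulder", "knee", "cervical", "lumbar", "thoracic", "abdomen",
  "metformin", "ramipril", "atorvastatin", "insulin", "amoxicillin",
  "1 mm st elevation", "fitness to drive")

syn_eponyms <- c(
  "Parkinson", "Homan", "Apgar", "Babinski", "Crohn", "Hodgkin", "Addison",
  "Cushing", "Graves", "Paget", "Barrett", "Wernicke", "Korsakoff",
  "Raynaud", "Sjogren", "Dupuytren", "Achilles", "Chvostek", "Trousseau",
  "Murphy", "McBurney", "Osler", "Marfan", "Kaposi", "Burkitt", "Wilson",
  "Huntington", "Alzheimer", "Tourette", "Gilbert", "Meniere", "Colles",
  "Pott", "Romberg", "Kernig", "Brudzinski", "Bouchard", "Heberden",
  "Virchow", "Gleason")

# Words the invented-entry generator must never produce.
syn_reserved_words <- function() {
  unique(c(
    syn_common_words, syn_do_not_remove, cf(syn_eponyms),
    cf(unlist(strsplit(syn_filler_sentences, "[^A-Za-z]+"))),
    names(month_names), names(month_abbrev),
    c("dr", "mr", "mrs", "ms", "prof", "daughter", "son", "mother", "father",
      "husband", "wife", "sister", "brother"),
    c("drive", "street", "road", "avenue", "boulevard", "crescent", "court",
      "lane", "at", "in", "of", "near", "from"),
    c("general", "memorial", "hospital", "imaging", "centre", "laboratory",
      "physiotherapy", "clinic", "radiology", "hardware", "foods", "motors",
      "books", "ontario", "tel", "fax", "pager", "cell", "hcn", "mrn",
      "dob", "re", "dear", "sincerely", "admitted", "discharged",
      "employer", "supplier")))
}

title_case <- function(x) {
  paste0(toupper(substr(x, 1, 1)), substr(x, 2, nchar(x)))
}

make_words <- function(n, n_syll = 2L, reserved = syn_reserved_words(),
                       taken = character()) {
  out <- character(0)
  guard <- 0L
  while (length(out) < n) {
    guard <- guard + 1L
    if (guard > 50000L) stop("could not generate enough distinct words")
    w <- paste(sample(syn_syllables, n_syll, replace = TRUE), collapse = "")
    if (w %in% reserved || w %in% taken || w %in% cf(out)) next
    out <- c(out, w)
  }
  title_case(out)
}

#' Generate synthetic source lexicon files
#'
#' Writes one-entry-per-line source lists (names, nicknames, provider names,
#' streets, municipalities, facilities by type, businesses, eponyms, common
#' words, do-not-remove) plus a compilation manifest. Collisions are planted
#' deliberately and logged: municipality/surname and business/municipality
#' overlaps (which compilation must route to the ambiguous lists),
#' name/common-word overlaps (which compilation must remove), business
#' entries that are pharmacies/insurance (dropped) or radiology/laboratory/
#' physiotherapy clinics (moved to facilities), and do-not-remove exemplars
#' planted on the business list (stripped at compile time).
#'
#' @param seed integer seed
#' @param out_dir output directory for the list files
#' @param sizes named list of per-list counts
#' @param collision_rate fraction of municipality/business entries planted as
#'   cross-list collisions
#' @return list with `manifest` (path to the YAML manifest), `dir`, and
#'   `planted` (data.frame of planted collisions with their expected fate)
#' @export
generate_lexicons <- function(seed = 1L, out_dir = tempfile("synlex"),
                              sizes = list(), collision_rate = 0.1) {
  sz <- utils::modifyList(list(
    first_female = 12L, first_male = 12L, last_unambiguous = 30L,
    name_ambiguous = 40L, name_popular = 8L, nickname = 12L,
    provider = 16L, street = 20L, municipality = 20L, business = 18L), sizes)
  stopifnot(all(unlist(sz) > 0L))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  withr::with_seed(seed, {
    taken <- character(0)
    gen <- function(n, n_syll = 2L) {
      w <- make_words(n, n_syll, taken = taken)
      taken <<- c(taken, cf(w))
      w
    }
    first_female <- gen(sz$first_female)
    first_male <- gen(sz$first_male)
    last_unamb <- gen(sz$last_unambiguous)
    amb_names <- gen(sz$name_ambiguous)
    popular <- gen(sz$name_popular)
    nickname <- gen(sz$nickname, 1L)
    provider <- gen(sz$provider)
    street <- gen(sz$street)
    municipality <- gen(sz$municipality)
    business_base <- gen(sz$business)
    fac_names <- gen(12L)

    planted <- list()
    plant <- function(entry, lists, fate) {
      planted[[length(planted) + 1L]] <<- data.frame(
        entry = entry, lists = lists, fate = fate, stringsAsFactors = FALSE)
    }

    # cross-list collisions -> ambiguous after compilation
    n_muni_coll <- max(1L, round(collision_rate * sz$municipality))
    muni_coll <- sample(amb_names, n_muni_coll)
    municipality <- unique(c(municipality, muni_coll))
    for (e in muni_coll) plant(e, "municipality+name_ambiguous",
                               "municipality_ambiguous")
    n_busi_coll <- max(1L, round(collision_rate * sz$business))
    busi_coll <- sample(setdiff(municipality, muni_coll), n_busi_coll)
    businesses <- unique(c(paste(business_base, sample(
      c("Hardware", "Foods", "Motors", "Books"), sz$business, replace = TRUE)),
      busi_coll))
    for (e in busi_coll) plant(e, "business+municipality", "business_ambiguous")

    # name/common-word collisions -> removed by common-word filtering
    common_coll <- c("Stone", "Hill", "Brown")
    amb_names_out <- c(amb_names, common_coll)
    for (e in common_coll) plant(e, "name_ambiguous+common_word", "removed")

    # eponym surnames planted on the ambiguous names list -> suppression path
    epo_coll <- c("Wilson", "Murphy")
    amb_names_out <- c(amb_names_out, epo_coll)
    for (e in epo_coll) plant(e, "name_ambiguous+eponym", "eponym_suppressed")

    # businesses that compilation must drop or move
    moved <- c(paste(fac_names[9], "Radiology"),
               paste(fac_names[10], "Medical Laboratory"),
               paste(fac_names[11], "Physiotherapy"))
    dropped <- c(paste(fac_names[12], "Pharmacy"),
                 paste(business_base[1], "Insurance"))
    businesses <- c(businesses, moved, dropped)
    for (e in moved) plant(e, "business", "moved_to_facility")
    for (e in dropped) plant(e, "business", "dropped")

    # do-not-remove exemplars planted on a detection list -> stripped
    dnr_plants <- c("Assessment", "Emergency", "ST")
    businesses <- c(businesses, dnr_plants)
    for (e in dnr_plants) plant(e, "business+do_not_remove", "stripped_by_dnr")

    facilities <- list(
      hospital = c(paste(fac_names[1:3], "General Hospital"),
                   paste(fac_names[4], "Memorial Hospital")),
      radiology_clinic = paste(fac_names[5], "Imaging Centre"),
      medical_laboratory = paste(fac_names[6], "Community Laboratory"),
      physiotherapy_clinic = paste(fac_names[7], "Physiotherapy Clinic"),
      other = paste(fac_names[8], "Walk In Clinic")
    )

    files <- list(
      name_unambiguous = last_unamb,
      name_first_female = first_female,
      name_first_male = first_male,
      name_ambiguous = amb_names_out,
      name_popular = popular,
      nickname = nickname,
      provider_name = provider,
      street = street,
      municipality = municipality,
      business = businesses,
      eponym = syn_eponyms,
      common_word = syn_common_words,
      do_not_remove = syn_do_not_remove
    )
    for (nm in names(files)) {
      writeLines(files[[nm]], file.path(out_dir, paste0(nm, ".txt")),
                 useBytes = TRUE)
    }
    for (tp in names(facilities)) {
      writeLines(facilities[[tp]],
                 file.path(out_dir, paste0("facility_", tp, ".txt")),
                 useBytes = TRUE)
    }
    manifest <- list(
      lists = stats::setNames(as.list(paste0(names(files), ".txt")),
                              names(files)),
      facilities = stats::setNames(
        as.list(paste0("facility_", names(facilities), ".txt")),
        names(facilities)),
      options = list(short_common_n = 40L)
    )
    manifest_path <- file.path(out_dir, "manifest.yaml")
    yaml::write_yaml(manifest, manifest_path)
    list(manifest = manifest_path, dir = out_dir,
         planted = do.call(rbind, planted))
  })
}

#' Corpus generation settings
#'
#' @param n_records number of records
#' @param note_type_mix named proportions over the six note types (must sum
#'   to 1)
#' @param phi_density named expected PHI mentions per record by category; a
#'   value of 0 removes that category entirely, values in (0, 1] are
#'   per-slot inclusion probabilities
#' @param decoy_density expected decoy snippets per record
#' @param ambiguity_rate fraction of extra (family-member) name mentions
#'   drawn from the ambiguous lists rather than the unambiguous pool
#' @param seed integer seed
#' @return a `CorpusSpec` list
#' @export
corpus_spec <- function(n_records = 50L,
                        note_type_mix = c(progress_note = 0.35,
                                          consult_letter = 0.2,
                                          referral_letter = 0.1,
                                          discharge_summary = 0.1,
                                          diagnostic_report = 0.15,
                                          cpp_entry = 0.1),
                        phi_density = c(patient_name = 1, provider_name = 1,
                                        family_name = 0.7, facility = 1,
                                        street = 1, municipality = 1,
                                        business = 0.5,
                                        health_card_number = 1,
                                        postal_code = 1, phone_number = 1,
                                        medical_record_number = 1,
                                        web_email = 0.5, date_of_birth = 1),
                        decoy_density = 0, ambiguity_rate = 0.6,
                        seed = 1L) {
  stopifnot(abs(sum(note_type_mix) - 1) < 1e-8, all(note_type_mix >= 0),
            all(phi_density >= 0), decoy_density >= 0,
            ambiguity_rate >= 0, ambiguity_rate <= 1)
  stopifnot(all(names(note_type_mix) %in% note_types()))
  structure(list(n_records = as.integer(n_records),
                 note_type_mix = note_type_mix, phi_density = phi_density,
                 decoy_density = decoy_density,
                 ambiguity_rate = ambiguity_rate, seed = as.integer(seed)),
            class = "CorpusSpec")
}

# Span builder: accumulates text pieces while recording gold PHI spans and
# decoy spans at exact offsets.
sb_new <- function() {
  b <- new.env(parent = emptyenv())
  b$parts <- character(0); b$pos <- 0L
  b$gold <- list(); b$decoys <- list()
  b
}
sb_txt <- function(b, s) {
  b$parts <- c(b$parts, s); b$pos <- b$pos + nchar(s); invisible(b)
}
sb_phi <- function(b, surface, category, class) {
  b$gold[[length(b$gold) + 1L]] <- data.frame(
    start = b$pos, end = b$pos + nchar(surface), category = category,
    rule_id = paste0("planted:", class), surface = surface,
    stringsAsFactors = FALSE)
  sb_txt(b, surface)
}
sb_decoy <- function(b, surface, kind) {
  b$decoys[[length(b$decoys) + 1L]] <- data.frame(
    start = b$pos, end = b$pos + nchar(surface), kind = kind,
    surface = surface, stringsAsFactors = FALSE)
  sb_txt(b, surface)
}
sb_build <- function(b) {
  list(text = paste(b$parts, collapse = ""),
       gold = if (length(b$gold)) do.call(rbind, b$gold) else empty_annotations(),
       decoys = if (length(b$decoys)) do.call(rbind, b$decoys) else
         data.frame(start = integer(), end = integer(), kind = character(),
                    surface = character(), stringsAsFactors = FALSE))
}

# Detection-relevant pools pulled from the compiled LexiconSet; the generator
# only plants surfaces the compiled lexicons actually contain.
corpus_context <- function(lexset) {
  pools <- surrogate_pools(lexset)
  amb_names <- lexset_entries(lexset, "patient_provider_name", "ambiguous")
  amb_names <- title_case(setdiff(amb_names, cf(syn_eponyms)))
  list(
    first_female = pools$first_female, first_male = pools$first_male,
    last = pools$last,
    amb_names = amb_names,
    muni_unamb = pools$municipality,
    muni_amb = title_case(lexset_entries(lexset, "municipality", "ambiguous")),
    business = pools$business,
    facility = lexset$lexicons$facility$entries,
    street = lexset$lexicons$street$entries
  )
}

rand_date_string <- function(years = 2005:2020) {
  sprintf("%02d/%02d/%04d", sample(1:12, 1), sample(1:28, 1), sample(years, 1))
}

rand_hcn <- function(variant = sample(1:3, 1)) {
  d <- paste(sample(0:9, 10, replace = TRUE), collapse = "")
  code <- paste(sample(LETTERS, 2, replace = TRUE), collapse = "")
  switch(variant,
         d,
         paste(substr(d, 1, 4), substr(d, 5, 7), substr(d, 8, 10)),
         paste0(substr(d, 1, 4), "-", substr(d, 5, 7), "-", substr(d, 8, 10),
                " ", code))
}

rand_phone <- function() {
  sprintf("(%d%d%d) %d%d%d-%d%d%d%d",
          sample(2:9, 1), sample(0:9, 1), sample(0:9, 1),
          sample(2:9, 1), sample(0:9, 1), sample(0:9, 1),
          sample(0:9, 1), sample(0:9, 1), sample(0:9, 1), sample(0:9, 1))
}

rand_mrn <- function() paste(sample(0:9, sample(5:9, 1), replace = TRUE),
                             collapse = "")

rand_email <- function() {
  w <- cf(make_words(2L, 2L))
  paste0(w[1], ".", w[2], "@", cf(make_words(1L, 2L)), ".com")
}

syn_decoy_bank <- function(allow_month_dates = FALSE) {
  bank <- list(
    list(surface = "Homan's sign negative.", kind = "eponym"),
    list(surface = "Parkinson's disease stable on treatment.", kind = "eponym"),
    list(surface = "Obstetric history G2P1A1.", kind = "obstetric"),
    list(surface = "No tenderness over C6C7T1.", kind = "spinal"),
    list(surface = "S1S2S4 on auscultation.", kind = "heart_sounds"),
    list(surface = "Counselled regarding fitness to drive.", kind = "street_guard"),
    list(surface = "Charted in S. O. A. P. format.", kind = "single_letter"),
    list(surface = "Sent to emergency for assessment.", kind = "do_not_remove"),
    list(surface = "1 mm ST elevation noted on ECG.", kind = "do_not_remove")
  )
  if (allow_month_dates) {
    bank <- c(bank, list(
      list(surface = "Letter of June 3, 2015 reviewed.", kind = "month_date"),
      list(surface = "Seen previously on March 14, 2012.", kind = "month_date")))
  }
  bank
}

#' Generate one synthetic record with gold annotations
#'
#' Fills a note-type-specific template with clinical filler and embeds, at
#' recorded offsets, the PHI mentions selected by the spec's densities
#' (structured-field-consistent patient/provider names, family-member names
#' with relation triggers, facility/street/municipality/business mentions,
#' health card numbers in all three format variants, postal codes, MRNs,
#' phones, emails/URLs, DOB and non-DOB dates) plus decoys per
#' `decoy_density`. Gold annotations cover exactly the planted PHI.
#'
#' @param spec a [corpus_spec()]
#' @param record_id record identifier
#' @param lexset the compiled synthetic `LexiconSet`
#' @param note_type note type (drawn from the mix by [generate_corpus()])
#' @return list with `record` (a `Record`), `gold` (annotations), and
#'   `decoys` (data.frame of protected snippets, including planted non-DOB
#'   dates with kind `"date"`)
#' @export
generate_record <- function(spec, record_id, lexset,
                            note_type = "progress_note") {
  ctx <- corpus_context(lexset)
  dens <- spec$phi_density
  want <- function(cat) {
    d <- dens[cat]
    !is.na(d) && d > 0 && stats::runif(1) < min(1, d)
  }
  phi_free <- all(dens == 0)

  gender <- sample(c("M", "F"), 1L)
  pat_first <- sample(if (gender == "M") ctx$first_male else ctx$first_female, 1L)
  pat_last <- sample(ctx$last, 1L)
  prov_last <- sample(ctx$amb_names, 1L)
  dob <- as.Date("1940-01-01") + sample.int(20000L, 1L)

  b <- sb_new()
  filler <- function() sb_txt(b, paste0(sample(syn_filler_sentences, 1L), " "))
  put_date <- function(prefix = "", suffix = " ") {
    d <- rand_date_string()
    # never collide with a DOB rendering
    while (d %in% dob_renderings(dob)) d <- rand_date_string()
    sb_txt(b, prefix); sb_decoy(b, d, "date"); sb_txt(b, suffix)
    d
  }
  put_family <- function() {
    rel <- title_case(sample(c("daughter", "son", "husband", "wife"), 1L))
    amb <- stats::runif(1) < spec$ambiguity_rate
    nm <- if (amb && length(ctx$amb_names)) sample(ctx$amb_names, 1L) else
      sample(ctx$last, 1L)
    sb_txt(b, paste0(rel, " "))
    sb_phi(b, nm, "patient_name", if (amb) "ambiguous" else "unambiguous")
    sb_txt(b, " was present at the visit. ")
  }
  put_patient <- function() {
    sb_phi(b, paste(pat_first, pat_last), "patient_name", "unambiguous")
  }
  put_provider <- function(last = prov_last) {
    sb_txt(b, "Dr. ")
    sb_phi(b, last, "provider_name", "ambiguous")
  }
  put_street <- function() {
    sb_phi(b, paste(sample(100:999, 1L), sample(ctx$street, 1L),
                    sample(c("Street", "Drive", "Avenue", "Road"), 1L)),
           "street", "unambiguous")
  }
  put_decoys <- function() {
    n <- stats::rpois(1L, spec$decoy_density)
    if (n <= 0) return(invisible())
    bank <- syn_decoy_bank(allow_month_dates = phi_free)
    for (d in sample(bank, min(n, length(bank)))) {
      sb_decoy(b, d$surface, d$kind); sb_txt(b, " ")
    }
    sb_txt(b, "\n")
  }

  header_address <- function() {
    if (want("facility")) {
      sb_phi(b, sample(ctx$facility, 1L), "facility", "unambiguous")
      sb_txt(b, "\n")
    }
    if (want("street")) { put_street(); sb_txt(b, "\n") }
    muni_line <- want("municipality")
    if (muni_line) {
      sb_phi(b, sample(ctx$muni_unamb, 1L), "municipality", "unambiguous")
      sb_txt(b, ", Ontario")
    }
    if (want("postal_code")) {
      sb_txt(b, if (muni_line) "  " else "")
      sb_phi(b, random_postal(TRUE), "postal_code", "pattern")
    }
    if (muni_line || TRUE) sb_txt(b, "\n")
    if (want("phone_number")) {
      sb_txt(b, "Tel: ")
      sb_phi(b, rand_phone(), "phone_number", "pattern")
      sb_txt(b, "\n")
    }
  }
  patient_line <- function() {
    if (want("patient_name")) {
      sb_txt(b, "Patient: "); put_patient()
    }
    if (want("health_card_number")) {
      sb_txt(b, "  HCN ")
      sb_phi(b, rand_hcn(), "health_card_number", "pattern")
    }
    if (want("medical_record_number")) {
      sb_txt(b, "  MRN ")
      sb_phi(b, rand_mrn(), "medical_record_number", "pattern")
    }
    sb_txt(b, "\n")
    if (want("date_of_birth")) {
      fmt <- sample(1:3, 1L)
      rend <- switch(fmt,
                     format(dob, "%m/%d/%Y"),
                     format(dob, "%Y-%m-%d"),
                     sprintf("%d/%d/%04d",
                             as.integer(format(dob, "%m")),
                             as.integer(format(dob, "%d")),
                             as.integer(format(dob, "%Y"))))
      sb_txt(b, "DOB: ")
      sb_phi(b, rend, "date_of_birth", "dob")
      sb_txt(b, "\n")
    }
  }
  body_common <- function() {
    filler()
    if (want("family_name")) put_family()
    if (want("municipality") && length(ctx$muni_amb) &&
        stats::runif(1) < spec$ambiguity_rate) {
      sb_txt(b, "Moved here from ")
      sb_phi(b, sample(ctx$muni_amb, 1L), "municipality", "ambiguous")
      sb_txt(b, " last year. ")
    }
    if (want("business")) {
      sb_txt(b, "Employer: ")
      sb_phi(b, sample(ctx$business, 1L), "business", "unambiguous")
      sb_txt(b, ". ")
    }
    filler()
    if (want("web_email")) {
      sb_txt(b, "Results sent to ")
      sb_phi(b, rand_email(), "web_email", "pattern")
      sb_txt(b, ". ")
    }
    sb_txt(b, "\n")
    put_decoys()
  }

  if (note_type %in% c("consult_letter", "referral_letter")) {
    header_address()
    put_date("", "\n\n")
    if (want("provider_name")) {
      sb_txt(b, "Dear "); put_provider(); sb_txt(b, ":\n")
    }
    sb_txt(b, "Re: ")
    patient_line()
    sb_txt(b, "\n")
    body_common()
    filler(); sb_txt(b, "\n")
    sb_txt(b, "Sincerely,\n")
    if (want("provider_name")) {
      put_provider(sample(ctx$amb_names, 1L)); sb_txt(b, "\n")
    }
  } else if (note_type == "discharge_summary") {
    sb_txt(b, "DISCHARGE SUMMARY\n")
    patient_line()
    if (want("facility")) {
      sb_txt(b, "Admitted to ")
      sb_phi(b, sample(ctx$facility, 1L), "facility", "unambiguous")
      put_date(" on ", ".\n")
    }
    body_common()
    put_date("Discharged ", ". ")
    if (want("provider_name")) {
      sb_txt(b, "Follow up with "); put_provider(); sb_txt(b, ".")
    }
    sb_txt(b, "\n")
  } else if (note_type == "diagnostic_report") {
    if (want("facility")) {
      sb_phi(b, sample(ctx$facility, 1L), "facility", "unambiguous")
      sb_txt(b, "\n")
    }
    put_date("Report date ", "\n")
    sb_txt(b, "Re: ")
    patient_line()
    sb_txt(b, "Hemoglobin 138 g/L. Glucose 5.2 mmol/L. TSH 2.1 mIU/L.\n")
    body_common()
  } else if (note_type == "cpp_entry") {
    sb_txt(b, "CPP - Past health: hypertension, type 2 diabetes.\n")
    sb_txt(b, "Family history: cardiac disease. ")
    if (want("family_name")) put_family()
    sb_txt(b, "\nAllergies: none known.\n")
    body_common()
  } else { # progress_note
    put_date("", "\n")
    sb_txt(b, "S: "); filler()
    if (want("family_name")) put_family()
    sb_txt(b, "\nO: BP 124/78, HR 72. ")
    filler(); sb_txt(b, "\n")
    sb_txt(b, "A: "); filler(); sb_txt(b, "\n")
    sb_txt(b, "P: ")
    if (want("phone_number")) {
      sb_txt(b, "Pharmacy fax ")
      sb_phi(b, rand_phone(), "phone_number", "pattern")
      sb_txt(b, ". ")
    }
    filler(); sb_txt(b, "\n")
    put_decoys()
  }

  built <- sb_build(b)
  rec <- new_record(record_id, built$text, note_type,
                    patient_first = pat_first, patient_last = pat_last,
                    provider_first = NA_character_, provider_last = prov_last,
                    gender = gender, dob = dob)
  gold <- built$gold
  if (nrow(gold)) check_annotations(gold, built$text)
  list(record = rec, gold = gold, decoys = built$decoys)
}

#' Generate a synthetic corpus
#'
#' Draws note types from the mix, generates each record with its gold
#' annotations and decoy log, and (optionally) writes the corpus to disk:
#' `records/<id>.txt`, `gold/<id>.tsv` (standoff annotations),
#' `decoys/<id>.tsv`, `sidecar.tsv`, and `manifest.json` with the spec, seed
#' and content checksums. Fully deterministic for a fixed spec.
#'
#' @param spec a [corpus_spec()]
#' @param lexset compiled synthetic `LexiconSet`
#' @param out_dir optional output directory
#' @return (invisibly when writing) list with `records`, `gold`, `decoys`
#'   (named lists keyed by record id), `sidecar` (data.frame), and `dir`
#' @export
generate_corpus <- function(spec, lexset, out_dir = NULL) {
  stopifnot(inherits(spec, "CorpusSpec"))
  res <- withr::with_seed(spec$seed, {
    ids <- sprintf("rec%04d", seq_len(spec$n_records))
    types <- sample(names(spec$note_type_mix), spec$n_records, replace = TRUE,
                    prob = spec$note_type_mix)
    out <- lapply(seq_len(spec$n_records), function(i) {
      generate_record(spec, ids[i], lexset, note_type = types[i])
    })
    names(out) <- ids
    out
  })
  records <- lapply(res, `[[`, "record")
  gold <- lapply(res, `[[`, "gold")
  decoys <- lapply(res, `[[`, "decoys")
  sidecar <- do.call(rbind, lapply(records, function(r) {
    data.frame(record_id = r$record_id, note_type = r$note_type,
               patient_first = r$patient_first, patient_last = r$patient_last,
               provider_first = r$provider_first,
               provider_last = r$provider_last, gender = r$gender,
               dob = format(r$dob, "%Y-%m-%d"), stringsAsFactors = FALSE)
  }))
  rownames(sidecar) <- NULL
  corpus <- list(records = records, gold = gold, decoys = decoys,
                 sidecar = sidecar, spec = spec, dir = out_dir)
  if (!is.null(out_dir)) {
    write_corpus(corpus, out_dir)
    return(invisible(corpus))
  }
  corpus
}
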