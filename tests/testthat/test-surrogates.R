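# Initial name removal and surrogate substitution contracts.

test_that("initial name removal erases structured names consistently", {
  set <- fixture_set()
  rec <- new_record("r1", "John Smith returns. JOHN was well; smith's chart.",
                    patient_first = "John", patient_last = "Smith",
                    provider_first = "Anne", provider_last = "Chu",
                    gender = "M")
  out <- initial_name_removal(rec, set, seed = 4L)
  expect_false(grepl("john|smith", tolower(out$text)))
  nm <- attr(out, "name_map")
  expect_identical(unname(nm$patient["original_first"]), "John")
  # the same fake name is used for every occurrence
  fake <- unname(nm$patient["fake_first"])
  expect_equal(lengths(regmatches(out$text, gregexpr(fake, out$text))), 2L)
  # determinism
  out2 <- initial_name_removal(rec, set, seed = 4L)
  expect_identical(out$text, out2$text)
  # name absent from text -> text unchanged
  rec3 <- new_record("r3", "no names here",
                     patient_first = "John", patient_last = "Smith",
                     provider_first = "Anne", provider_last = "Chu")
  expect_identical(initial_name_removal(rec3, set, seed = 1L)$text,
                   "no names here")
  rec4 <- new_record("r4", "text", patient_first = NA, patient_last = NA,
                     provider_first = "Anne", provider_last = "Chu")
  expect_warning(initial_name_removal(rec4, set, seed = 1L), "empty")
})

test_that("tag mode replaces each span with its category tag", {
  set <- fixture_set()
  txt <- "Seen at M4N 3M5 by staff."
  ann <- find_postal_codes(txt)
  res <- replace_phi(txt, ann, set, seed = 1L, mode = "tag")
  expect_identical(res$text, "Seen at [[postal_code]] by staff.")
})

test_that("pseudonym mode is format-preserving and consistent", {
  set <- fixture_set()
  txt <- "Codes M4N 3M5 and M4N 3M5; HCN 1234 567 890; MRN 84739."
  ann <- resolve_overlaps(bind_ann <- rbind(
    find_postal_codes(txt), find_health_card_numbers(txt),
    find_medical_record_numbers(txt)))
  res <- replace_phi(txt, ann, set, seed = 9L)
  # postal surrogate keeps letter-digit alternation with one space
  pc <- res$surrogate_map$surrogate[res$surrogate_map$category == "postal_code"]
  expect_match(pc, "^[A-Za-z][0-9][A-Za-z] [0-9][A-Za-z][0-9]$")
  expect_false(identical(pc, "M4N 3M5"))
  # identical surfaces -> identical surrogates (one map entry, used twice)
  expect_equal(sum(res$surrogate_map$category == "postal_code"), 1L)
  expect_equal(lengths(regmatches(res$text, gregexpr(pc, res$text,
                                                     fixed = TRUE))), 2L)
  # digit-grouping shapes preserved
  hc <- res$surrogate_map$surrogate[res$surrogate_map$category ==
                                      "health_card_number"]
  expect_match(hc, "^[0-9]{4} [0-9]{3} [0-9]{3}$")
  mr <- res$surrogate_map$surrogate[res$surrogate_map$category ==
                                      "medical_record_number"]
  expect_match(mr, "^[0-9]{5}$")
})

test_that("non-PHI characters are byte-identical and the edit list is exact", {
  set <- fixture_set()
  corp <- fixture_corpus()
  res <- fixture_results()
  for (id in utils::head(names(corp$records), 25)) {
    r <- res[[id]]
    orig <- r$scanned_text
    ann <- r$annotations
    # reconstruct the output from original text + edit list
    pieces <- character(0); pos <- 0L
    for (i in seq_len(nrow(ann))) {
      pieces <- c(pieces, substring(orig, pos + 1L, ann$start[i]),
                  r$edits$surrogate[i])
      pos <- ann$end[i]
    }
    rebuilt <- paste(c(pieces, substring(orig, pos + 1L, nchar(orig))),
                     collapse = "")
    expect_identical(rebuilt, r$text)
    # edit offsets locate each surrogate in the new text
    for (i in seq_len(nrow(r$edits))) {
      e <- r$edits[i, ]
      expect_identical(substring(r$text, e$new_start + 1L, e$new_end),
                       e$surrogate)
    }
  }
})

test_that("same seed gives identical results; zero annotations is identity", {
  set <- fixture_set()
  corp <- fixture_corpus()
  rec <- corp$records[[5]]
  ann <- phi_scan(rec, set)
  a <- replace_phi(rec, ann, set, seed = 77L)
  b <- replace_phi(rec, ann, set, seed = 77L)
  expect_identical(a$text, b$text)
  expect_identical(a$surrogate_map, b$surrogate_map)

  none <- replace_phi(rec, empty_annotations(), set, seed = 1L)
  expect_identical(none$text, rec$text)

  overlapping <- new_annotations(c(0L, 2L), c(5L, 7L), "patient_name", "t",
                                 rec$text)
  expect_error(replace_phi(rec, overlapping, set, seed = 1L), "disjoint")
})

test_that("re-scanning pseudonymized output annotates only surrogate positions", {
  set <- fixture_set()
  corp <- fixture_corpus()
  res <- fixture_results()
  for (id in utils::head(names(corp$records), 30)) {
    r <- res[[id]]
    rec2 <- corp$records[[id]]
    rec2$text <- r$text
    ann2 <- phi_scan(rec2, set)
    if (nrow(ann2) == 0L) next
    sur <- data.frame(start = r$edits$new_start, end = r$edits$new_end)
    outside <- vapply(seq_len(nrow(ann2)), function(i) {
      !any(ann2$start[i] < sur$end & sur$start < ann2$end[i])
    }, logical(1))
    expect_equal(sum(outside), 0L)
  }
})

test_that("name surrogates are gender-matched when gender is known", {
  set <- fixture_set()
  pools_f <- tolower(set$lexicons$name_first_female$entries)
  pools_m <- tolower(set$lexicons$name_first_male$entries)
  txt <- "Pt Zara here"
  ann <- new_annotations(3L, 7L, "patient_name", "t", txt)
  rec_f <- new_record("f", txt, gender = "F")
  rec_m <- new_record("m", txt, gender = "M")
  for (s in 1:5) {
    rf <- replace_phi(rec_f, ann, set, seed = s)
    expect_true(tolower(rf$surrogate_map$surrogate) %in% pools_f)
    rm_ <- replace_phi(rec_m, ann, set, seed = s)
    expect_true(tolower(rm_$surrogate_map$surrogate) %in% pools_m)
  }
})

test_that("facility surrogates share the original facility type", {
  set <- fixture_set()
  fac <- set$lexicons$facility
  types <- fac$facility_type[tolower(fac$entries)]
  orig <- fac$entries[types == "radiology_clinic"][1]
  txt <- paste0("Seen at ", orig, " today")
  ann <- new_annotations(8L, 8L + nchar(orig), "facility", "t", txt)
  for (s in 1:6) {
    r <- replace_phi(txt, ann, set, seed = s)
    sur <- r$surrogate_map$surrogate
    expect_identical(unname(fac$facility_type[tolower(sur)]),
                     "radiology_clinic")
    expect_false(identical(sur, orig))
  }
})
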