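# Lexicon construction and compilation rules.

test_that("load_lexicon trims, case-folds duplicates, and skips comments", {
  f <- withr::local_tempfile(lines = c("Toronto", "toronto", "# comment", ""))
  lex <- load_lexicon(f, "municipality", "unambiguous")
  expect_length(lex$entries, 1L)
  expect_identical(lex$entries, "Toronto")

  f3 <- withr::local_tempfile(lines = c("Alpha", "Beta", "Gamma"))
  expect_length(load_lexicon(f3, "municipality", "unambiguous")$entries, 3L)

  fe <- withr::local_tempfile(lines = character())
  expect_warning(lex0 <- load_lexicon(fe, "street", "unambiguous"), "empty")
  expect_length(lex0$entries, 0L)

  expect_error(load_lexicon(file.path(tempdir(), "no-such-file.txt"),
                            "street", "unambiguous"), "not found")
})

test_that("split_ambiguous partitions the target by cross-list membership", {
  target <- new_lexicon("businesses", "business", "unambiguous",
                        c("Acme", "Windsor"))
  others <- list(new_lexicon("muni", "municipality", "unambiguous", "Windsor"))
  sp <- split_ambiguous(target, others)
  expect_identical(sp$ambiguous$entries, "Windsor")
  expect_identical(sp$unambiguous$entries, "Acme")

  sp0 <- split_ambiguous(target, list())
  expect_length(sp0$ambiguous$entries, 0L)
  expect_identical(sp0$unambiguous$entries, target$entries)
})

test_that("split_ambiguous matches a brute-force membership audit on random lists", {
  withr::with_seed(99, {
    for (rep in 1:10) {
      vocab <- replicate(120, paste(sample(letters, 6), collapse = ""))
      tgt <- sample(vocab, 50)
      planted <- sample(tgt, 10)
      other <- unique(c(sample(setdiff(vocab, tgt), 40), toupper(planted)))
      target <- new_lexicon("t", "municipality", "unambiguous", tgt)
      others <- list(new_lexicon("o", "business", "unambiguous", other))
      sp <- split_ambiguous(target, others)
      # brute force: nested loop membership
      expected_amb <- character()
      for (e in target$entries) {
        hit <- FALSE
        for (o in other) if (tolower(e) == tolower(o)) hit <- TRUE
        if (hit) expected_amb <- c(expected_amb, e)
      }
      expect_setequal(sp$ambiguous$entries, expected_amb)
      expect_setequal(c(sp$ambiguous$entries, sp$unambiguous$entries),
                      target$entries)
      expect_length(intersect(tolower(sp$ambiguous$entries),
                              tolower(sp$unambiguous$entries)), 0L)
      expect_length(sp$ambiguous$entries, 10L)
    }
  })
})

test_that("filter_common_words removes case-folded collisions", {
  names_lex <- new_lexicon("n", "patient_provider_name", "unambiguous",
                           c("Smith", "Drive", "Park"))
  common <- new_lexicon("c", "common_word", "protective", c("drive", "park"))
  expect_identical(filter_common_words(names_lex, common)$entries, "Smith")
  empty_common <- new_lexicon("c", "common_word", "protective", character())
  expect_identical(filter_common_words(names_lex, empty_common)$entries,
                   names_lex$entries)

  withr::with_seed(7, {
    base <- replicate(100, paste(sample(letters, 7), collapse = ""))
    coll <- sample(base, 25)
    lex <- new_lexicon("n", "patient_provider_name", "ambiguous", base)
    common2 <- new_lexicon("c", "common_word", "protective",
                           c(toupper(coll), "zzz"))
    expect_length(filter_common_words(lex, common2)$entries, 75L)
  })
})

test_that("filter_common_words short mode uses only the top of the list", {
  lex <- new_lexicon("n", "patient_provider_name", "unambiguous",
                     c("alpha", "omega"))
  common <- new_lexicon("c", "common_word", "protective",
                        c("alpha", "beta", "omega"))
  out <- filter_common_words(lex, common, mode = "short", short_n = 2L)
  expect_identical(out$entries, "omega")  # "omega" is below the cut
})

test_that("apply_name_precedence deletes popular names and resolves overlap", {
  pop <- new_lexicon("p", "patient_provider_name", "popular", "john")
  una <- new_lexicon("u", "patient_provider_name", "unambiguous",
                     c("john", "zyxil"))
  amb <- new_lexicon("a", "patient_provider_name", "ambiguous",
                     c("john", "may", "zyxil"))
  out <- apply_name_precedence(pop, una, amb)
  expect_identical(out$unambiguous$entries, "zyxil")
  expect_identical(out$ambiguous$entries, "may")

  dis <- apply_name_precedence(
    new_lexicon("p", "patient_provider_name", "popular", "aa"),
    new_lexicon("u", "patient_provider_name", "unambiguous", "bb"),
    new_lexicon("a", "patient_provider_name", "ambiguous", "cc"))
  expect_identical(dis$unambiguous$entries, "bb")
  expect_identical(dis$ambiguous$entries, "cc")
})

test_that("merge_nicknames unions case-insensitively", {
  amb <- new_lexicon("a", "patient_provider_name", "ambiguous", "rob")
  nick <- new_lexicon("n", "nickname", "protective", c("bob", "Rob"))
  expect_setequal(merge_nicknames(amb, nick)$entries, c("rob", "bob"))
  empty_nick <- new_lexicon("n", "nickname", "protective", character())
  expect_identical(merge_nicknames(amb, empty_nick)$entries, amb$entries)

  withr::with_seed(21, {
    a <- replicate(80, paste(sample(letters, 8), collapse = ""))
    extra <- replicate(25, paste(sample(LETTERS, 8), collapse = ""))
    n <- c(sample(a, 15), extra)
    m <- merge_nicknames(
      new_lexicon("a", "patient_provider_name", "ambiguous", a),
      new_lexicon("n", "nickname", "protective", n))
    expect_length(m$entries, 105L)
  })
})

test_that("compile_lexicon_set satisfies the set invariants and is reproducible", {
  gen <- fixture_gen()
  set <- fixture_set()
  expect_true(validate_lexicon_set(set))
  set2 <- compile_lexicon_set(gen$manifest)
  expect_identical(set$checksum, set2$checksum)

  planted <- gen$planted
  muni_amb <- lexset_entries(set, "municipality", "ambiguous")
  for (e in planted$entry[planted$fate == "municipality_ambiguous"]) {
    expect_true(tolower(e) %in% muni_amb)
  }
  busi_amb <- lexset_entries(set, "business", "ambiguous")
  for (e in planted$entry[planted$fate == "business_ambiguous"]) {
    expect_true(tolower(e) %in% busi_amb)
  }
  all_names <- lexset_entries(set, "patient_provider_name")
  for (e in planted$entry[planted$fate == "removed"]) {
    expect_false(tolower(e) %in% all_names)
  }
  # moved radiology/laboratory/physiotherapy entries live on the facility list
  fac <- lexset_entries(set, "facility")
  busi <- lexset_entries(set, "business")
  for (e in planted$entry[planted$fate == "moved_to_facility"]) {
    expect_true(tolower(e) %in% fac)
    expect_false(tolower(e) %in% busi)
  }
  for (e in planted$entry[planted$fate == "dropped"]) {
    expect_false(tolower(e) %in% c(busi, fac))
  }
  # do-not-remove exemplars stripped from detection lists
  for (e in planted$entry[planted$fate == "stripped_by_dnr"]) {
    expect_false(tolower(e) %in% c(busi, fac, all_names))
    expect_true(tolower(e) %in% lexset_entries(set, "do_not_remove"))
  }
})

test_that("a business entry equal to a municipality entry lands in ambiguous businesses", {
  d <- withr::local_tempdir()
  write_list <- function(name, entries) {
    writeLines(entries, file.path(d, paste0(name, ".txt")))
    paste0(name, ".txt")
  }
  manifest <- list(
    lists = list(
      name_unambiguous = write_list("nu", c("Zorvan")),
      name_ambiguous = write_list("na", c("Kelmor")),
      name_popular = write_list("np", c("Quintos")),
      nickname = write_list("ni", character(0)) ,
      street = write_list("st", c("Velmor")),
      municipality = write_list("mu", c("Windsorix", "Barville")),
      business = write_list("bu", c("Windsorix", "Acme Hardware")),
      eponym = write_list("ep", c("Homan")),
      common_word = write_list("cw", c("the", "and")),
      do_not_remove = write_list("dn", c("assessment"))
    ),
    facilities = list(hospital = write_list("fh", c("Barville General Hospital"))),
    options = list(short_common_n = 2)
  )
  suppressWarnings(set <- compile_lexicon_set(manifest, base_dir = d))
  expect_true("windsorix" %in% lexset_entries(set, "business", "ambiguous"))
  expect_true("acme hardware" %in% lexset_entries(set, "business", "unambiguous"))
  suppressWarnings(expect_error(
    compile_lexicon_set(utils::modifyList(
      manifest, list(lists = utils::modifyList(manifest$lists,
                                               list(street = "missing.txt")))),
      base_dir = d),
    "missing"))
})

test_that("LexiconSet round-trips through its serialized directory form", {
  set <- fixture_set()
  d <- withr::local_tempdir()
  write_lexicon_set(set, d)
  back <- suppressWarnings(read_lexicon_set(d))
  expect_identical(back$checksum, set$checksum)
  expect_setequal(names(back$lexicons), names(set$lexicons))
  expect_identical(sort(back$lexicons$facility$entries),
                   sort(set$lexicons$facility$entries))
  expect_true(validate_lexicon_set(back))
})
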