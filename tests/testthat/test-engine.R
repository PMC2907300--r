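# Tokenizer, name/location detection, overrides, overlap resolution, scan.

test_that("tokenize separates punctuation and preserves offsets", {
  tok <- tokenize("Dr. Smith")
  expect_identical(tok$surface, c("Dr", ".", "Smith"))
  expect_equal(tok$start, c(0L, 2L, 4L))
  expect_equal(tok$end, c(2L, 3L, 9L))
  expect_equal(nrow(tokenize("")), 0L)
  expect_identical(tokenize("Parkinson's")$surface, "Parkinson's")
  expect_identical(tokenize("Operative-Smith")$surface, "Operative-Smith")
})

test_that("tokenization round-trips arbitrary text", {
  for (seed in 1:5) {
    txt <- random_token_text(1000L, seed)
    tok <- tokenize(txt)
    expect_identical(tok$surface, substring(txt, tok$start + 1L, tok$end))
    expect_true(all(tok$start[-1] >= tok$end[-nrow(tok)]))
    # gaps between tokens (and around them) contain only whitespace
    bounds <- c(0L, rbind(tok$start, tok$end), nchar(txt))
    gaps <- substring(txt, bounds[seq(1, length(bounds) - 1, by = 2)] + 1L,
                      bounds[seq(2, length(bounds), by = 2)])
    expect_true(all(grepl("^\\s*$", gaps)))
    # reconstruction: tokens + gaps concatenate back to the input
    rebuilt <- paste0(paste0(gaps[-length(gaps)], tok$surface, collapse = ""),
                      gaps[length(gaps)])
    expect_identical(rebuilt, txt)
  }
})

make_name_set <- function() {
  new_lexicon_set(list(
    name_unambiguous = new_lexicon("name_unambiguous",
                                   "patient_provider_name", "unambiguous",
                                   c("Zorvan", "Quell")),
    name_ambiguous = new_lexicon("name_ambiguous", "patient_provider_name",
                                 "ambiguous", c("Emily", "Smith", "Jones",
                                                "Homan", "Parkinson")),
    eponym = new_lexicon("eponym", "eponym", "protective",
                         c("Homan", "Parkinson")),
    street = new_lexicon("street", "street", "unambiguous", "Bathurst"),
    municipality = new_lexicon("municipality", "municipality", "unambiguous",
                               "Barville"),
    municipality_amb = new_lexicon("municipality_amb", "municipality",
                                   "ambiguous", "Windsorix"),
    business = new_lexicon("business", "business", "unambiguous",
                           "Acme Hardware"),
    facility = new_lexicon("facility", "facility", "unambiguous",
                           "Toronto General Hospital"),
    do_not_remove = new_lexicon("do_not_remove", "do_not_remove", "protective",
                                c("assessment", "emergency", "st",
                                  "1 mm st elevation"))
  ))
}

test_that("ambiguous names need a trigger or name adjacency; unambiguous never do", {
  set <- make_name_set()
  scan1 <- function(txt) {
    detect_names(tokenize(txt), set, engine_config(), txt)
  }
  expect_identical(scan1("seen with daughter Emily today")$surface, "Emily")
  expect_equal(nrow(scan1("Emily was normal")), 0L)
  expect_identical(scan1("Dr. Smith reviewed")$surface, "Smith")
  expect_identical(scan1("Dr. Smith reviewed")$category, "provider_name")
  expect_identical(scan1("met Zorvan downtown")$surface, "Zorvan")
  # adjacent ambiguous names qualify each other and merge
  expect_identical(scan1("note from Emily Smith today")$surface, "Emily Smith")
  # merged unambiguous pair
  expect_identical(scan1("pt Quell Zorvan here")$surface, "Quell Zorvan")
})

test_that("eponyms, single letters and hyphenated words are protected", {
  set <- make_name_set()
  scan1 <- function(txt) detect_names(tokenize(txt), set, engine_config(), txt)
  expect_equal(nrow(scan1("Homan's sign positive")), 0L)
  expect_equal(nrow(scan1("Mr. Parkinson's disease")), 0L)
  # single letter followed by punctuation is never a name, even if listed
  set2 <- make_name_set()
  set2$lexicons$name_unambiguous$entries <- c("Q", "Zorvan")
  expect_equal(nrow(detect_names(tokenize("Q. 4 weeks"), set2,
                                 engine_config(), "Q. 4 weeks")), 0L)
  # Operative-Smith is not a hyphenated surname; Smith-Jones is
  expect_equal(nrow(scan1("Operative-Smith noted")), 0L)
  ann <- scan1("Mrs. Smith-Jones visited")
  expect_identical(ann$surface, "Smith-Jones")
})

test_that("suppress_eponyms drops exactly the planted eponym candidates", {
  withr::with_seed(31, {
    surf <- c(replicate(13, paste(sample(LETTERS, 6), collapse = "")),
              sample(c("Homan's", "Parkinson", "Apgar", "Crohn's", "Graves",
                       "Paget", "Osler"), 7))
    txt <- paste(surf, collapse = " ")
    tok <- tokenize(txt)
    cand <- new_annotations(tok$start, tok$end, "patient_name", "t", txt)
    epo <- new_lexicon("e", "eponym", "protective",
                       c("Homan", "Parkinson", "Apgar", "Crohn", "Graves",
                         "Paget", "Osler"))
    kept <- suppress_eponyms(cand, epo)
    expect_equal(nrow(kept), 13L)
  })
})

test_that("locations: unambiguous always, ambiguous with corroboration, streets gated", {
  set <- make_name_set()
  scan1 <- function(txt) {
    detect_locations(tokenize(txt), set, engine_config(), txt)
  }
  ann <- scan1("admitted to Toronto General Hospital overnight")
  expect_identical(ann$surface, "Toronto General Hospital")
  expect_identical(ann$category, "facility")

  expect_equal(nrow(scan1("fitness to drive assessed")), 0L)
  a2 <- scan1("at 399 Bathurst Street, Toronto")
  expect_identical(a2$surface, "399 Bathurst Street")
  expect_identical(a2$category, "street")
  expect_equal(nrow(scan1("Bathurst alone, no suffix")), 0L)

  expect_identical(scan1("lives in Windsorix now")$surface, "Windsorix")
  expect_equal(nrow(scan1("Windsorix was mentioned")), 0L)
  # postal-code adjacency corroborates an ambiguous mention
  a3 <- scan1("Windsorix M4N 3M5")
  expect_true("Windsorix" %in% a3$surface)
  expect_identical(scan1("sells at Acme Hardware weekly")$surface,
                   "Acme Hardware")
})

test_that("do-not-remove overrides every candidate it covers", {
  set <- make_name_set()
  txt <- "for assessment in emergency with 1 mm ST elevation"
  tok <- tokenize(txt)
  w <- tok[tok$is_word, ]
  cand <- new_annotations(w$start, w$end, "patient_name", "t", txt)
  kept <- apply_do_not_remove(cand, set, txt)
  expect_false("assessment" %in% kept$surface)
  expect_false("emergency" %in% kept$surface)
  expect_false("ST" %in% kept$surface)    # single entry and phrase cover
  expect_true("for" %in% kept$surface)    # untouched candidates pass through
})

test_that("resolve_overlaps keeps longer spans and yields disjoint output", {
  txt <- paste(rep("x", 40), collapse = "")
  a <- new_annotations(c(4L, 4L), c(9L, 20L), "patient_name", "t", txt)
  out <- resolve_overlaps(a)
  expect_equal(nrow(out), 1L)
  expect_equal(out$end, 20L)

  b <- new_annotations(c(0L, 10L), c(5L, 15L), "patient_name", "t", txt)
  expect_equal(nrow(resolve_overlaps(b)), 2L)

  withr::with_seed(17, {
    for (rep in 1:50) {
      n <- sample(3:12, 1)
      s <- sample(0:35, n, replace = TRUE)
      e <- pmin(40L, s + sample(1:8, n, replace = TRUE))
      cand <- new_annotations(s, e, sample(phi_categories(), n, replace = TRUE),
                              "t", txt)
      out <- resolve_overlaps(cand)
      if (nrow(out) > 1L) {
        expect_true(all(out$start[-1] >= out$end[-nrow(out)]))
      }
      expect_true(all(out$end <= 40L))
    }
  })
})

test_that("scan handles empty text and is deterministic and line-bounded", {
  set <- fixture_set()
  rec <- new_record("r0", "")
  expect_equal(nrow(phi_scan(rec, set)), 0L)

  corp <- fixture_corpus()
  rec1 <- corp$records[[1]]
  a <- phi_scan(rec1, set)
  b <- phi_scan(rec1, set)
  expect_identical(a, b)
  # no annotation spans a newline
  expect_false(any(grepl("\n", a$surface, fixed = TRUE)))
  expect_true(all(a$start[-1] >= a$end[-nrow(a)]))
})

test_that("a decoy-only note yields zero annotations", {
  set <- fixture_set()
  txt <- paste(
    "Homan's sign positive. G2P1A1. C6C7T1 tenderness. S1S2S4 noted.",
    "Counselled on fitness to drive. S. O. A. P. charting.",
    "Sent to emergency for assessment. 1 mm ST elevation. June 3, 2015.",
    sep = "\n")
  rec <- new_record("d1", normalize_month_dates(txt)$text)
  expect_equal(nrow(phi_scan(rec, set)), 0L)
})

test_that("growing an unambiguous lexicon never removes other annotations", {
  set <- fixture_set()
  corp <- fixture_corpus()
  rec <- corp$records[[3]]
  before <- phi_scan(rec, set)
  set2 <- set
  set2$lexicons$name_unambiguous$entries <-
    c(set2$lexicons$name_unambiguous$entries, "Qwyxotl")
  after <- phi_scan(rec, set2)
  key <- function(a) paste(a$start, a$end, a$category)
  expect_true(all(key(before) %in% key(after)))
})
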