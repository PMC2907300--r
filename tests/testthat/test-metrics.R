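# Token alignment, confusion counts, the five measures, error reports.

test_that("align_tokens gives any-overlap credit and skips punctuation", {
  txt <- "Dr. Smith saw Mary Jones."
  gold <- new_annotations(14L, 24L, "patient_name", "g", txt)   # "Mary Jones"
  pred <- new_annotations(14L, 18L, "patient_name", "p", txt)   # "Mary"
  al <- align_tokens(txt, gold, pred)
  expect_false(any(al$surface %in% c(".", ",")))
  mary <- al[al$surface == "Mary", ]
  jones <- al[al$surface == "Jones", ]
  expect_true(mary$gold && mary$pred)
  expect_true(jones$gold && !jones$pred)

  al0 <- align_tokens(txt, empty_annotations(), empty_annotations())
  expect_false(any(al0$gold) || any(al0$pred))
  expect_error(align_tokens(txt, new_annotations(0L, 999L, "patient_name",
                                                 "g", surface = "x"),
                            empty_annotations()),
               "bounds")
})

test_that("confusion counts match an independent tally on random vectors", {
  pairs <- data.frame(gold = c(TRUE, FALSE, TRUE, FALSE),
                      pred = c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(confusion(pairs), c(tp = 1L, fp = 1L, fn = 1L, tn = 1L))
  expect_equal(sum(confusion(pairs)), nrow(pairs))
  expect_equal(confusion(data.frame(gold = logical(), pred = logical())),
               c(tp = 0L, fp = 0L, fn = 0L, tn = 0L))

  withr::with_seed(3, {
    g <- stats::runif(1000) < 0.3
    p <- stats::runif(1000) < 0.4
    cts <- confusion(data.frame(gold = g, pred = p))
    # independent loop tally
    tally <- c(tp = 0L, fp = 0L, fn = 0L, tn = 0L)
    for (i in seq_along(g)) {
      k <- if (g[i] && p[i]) "tp" else if (!g[i] && p[i]) "fp"
      else if (g[i] && !p[i]) "fn" else "tn"
      tally[k] <- tally[k] + 1L
    }
    expect_equal(cts, tally)
  })
})

test_that("the five measures follow their definitions", {
  m <- compute_metrics(c(tp = 8, fp = 2, fn = 1, tn = 9))
  expect_equal(m$sensitivity, 8 / 9)
  expect_equal(m$specificity, 9 / 11)
  expect_equal(m$precision, 0.8)
  expect_equal(m$accuracy, 0.85)
  expect_equal(m$f_measure, 2 * 0.8 * (8 / 9) / (0.8 + 8 / 9))

  perfect <- compute_metrics(c(tp = 10, fp = 0, fn = 0, tn = 10))
  expect_equal(unlist(perfect[c("sensitivity", "specificity", "precision",
                                "accuracy", "f_measure")]),
               c(sensitivity = 1, specificity = 1, precision = 1,
                 accuracy = 1, f_measure = 1))

  # zero denominators are not-applicable, never 0
  none <- compute_metrics(c(tp = 0, fp = 0, fn = 0, tn = 5))
  expect_true(is.na(none$sensitivity))
  expect_true(is.na(none$precision))
  expect_error(compute_metrics(c(tp = 0, fp = 0, fn = 0, tn = 0)), "zero")

  expect_equal(round(f_from_pr(0.913, 0.883), 2), 0.90)
  expect_equal(f_from_pr(0, 0), 0)
})

test_that("swapping gold and predicted swaps fp/fn and precision/sensitivity", {
  txt <- paste(letters, collapse = " ")
  g <- new_annotations(c(0L, 4L), c(1L, 5L), "patient_name", "g", txt)
  p <- new_annotations(c(4L, 8L), c(5L, 9L), "patient_name", "p", txt)
  c1 <- confusion(align_tokens(txt, g, p))
  c2 <- confusion(align_tokens(txt, p, g))
  expect_equal(c1[["fp"]], c2[["fn"]])
  expect_equal(c1[["fn"]], c2[["fp"]])
  m1 <- compute_metrics(c1); m2 <- compute_metrics(c2)
  expect_equal(m1$precision, m2$sensitivity)
  expect_equal(m1$sensitivity, m2$precision)
})

test_that("error_report groups recurrent errors by surface with context", {
  txt <- "assessment one assessment two assessment Emily end"
  pred_spans <- gregexpr("assessment", txt, fixed = TRUE)[[1]]
  pred <- new_annotations(as.integer(pred_spans) - 1L,
                          as.integer(pred_spans) - 1L + 10L,
                          "business", "lex:business_unambiguous", txt)
  emily <- regexpr("Emily", txt, fixed = TRUE)
  gold <- new_annotations(as.integer(emily) - 1L, as.integer(emily) + 4L,
                          "patient_name", "g", txt)
  rep <- error_report(txt, gold, pred)
  expect_equal(nrow(rep$fp), 1L)
  expect_equal(rep$fp$count, 3L)
  expect_identical(rep$fp$surface, "assessment")
  expect_identical(rep$fp$rule_ids, "lex:business_unambiguous")
  expect_equal(nrow(rep$fn), 1L)
  expect_identical(rep$fn$surface, "emily")
  expect_true(grepl("Emily", rep$fn$contexts))

  clean <- error_report(txt, gold, gold)
  expect_equal(nrow(clean$fp), 0L)
  expect_equal(nrow(clean$fn), 0L)
})

test_that("evaluate_corpus pools token counts additively", {
  txt <- "alpha beta gamma delta epsilon zeta eta theta iota kappa"
  g <- new_annotations(0L, 5L, "patient_name", "g", txt)
  records <- list(r1 = new_record("r1", txt), r2 = new_record("r2", txt))
  gold <- list(r1 = g, r2 = g)
  pred <- list(r1 = g, r2 = g)
  ev <- evaluate_corpus(records, gold, pred)
  expect_equal(ev$metrics$sensitivity, 1)
  expect_equal(unname(ev$metrics$counts["tp"]), 2L)
  expect_equal(unname(ev$metrics$counts["tn"]), 18L)
  expect_equal(Reduce(`+`, lapply(seq_len(nrow(ev$per_record)), function(i)
    unlist(ev$per_record[i, c("tp", "fp", "fn", "tn")]))),
    unlist(as.list(ev$metrics$counts)), ignore_attr = TRUE)

  expect_warning(ev2 <- evaluate_corpus(records, gold["r1"], pred), "excluded")
  expect_identical(ev2$missing, "r2")
})

test_that("pooled corpus counts equal the sum of per-record counts on generated data", {
  corp <- fixture_corpus()
  res <- fixture_results()
  ids <- utils::head(names(corp$records), 100)
  ev <- evaluate_corpus(corp$records[ids], corp$gold[ids],
                        lapply(res[ids], `[[`, "annotations"))
  per_sum <- colSums(ev$per_record[, c("tp", "fp", "fn", "tn")])
  expect_equal(unname(per_sum), unname(unlist(ev$metrics$counts)))
  # per-category counts exist for every annotated category
  expect_true(all(c("patient_name", "health_card_number") %in%
                    names(ev$metrics$per_category)))
})

test_that("published benchmark rows are internally consistent under the F formula", {
  b <- deid_benchmark_rows()
  f <- f_from_pr(b$precision_pct / 100, b$sensitivity_pct / 100)
  expect_true(all(abs(f - b$f_measure) <= 0.005))
  expect_true(all(pmin(b$precision_pct, b$sensitivity_pct) / 100 <= f + 1e-12 &
                    f <= pmax(b$precision_pct, b$sensitivity_pct) / 100 + 1e-12))
})
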