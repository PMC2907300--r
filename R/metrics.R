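# Token-level evaluation against a reference standard: confusion counts, the
# five performance measures, and the false-positive/false-negative error
# reports that drive the iterative list-correction workflow.

#' Align gold and predicted annotations at the token level
#'
#' Tokenizes the text and labels each token gold-positive if any gold span
#' overlaps it and predicted-positive if any predicted span overlaps it
#' (any-overlap credit). Punctuation-only tokens are excluded from scoring by
#' default, so they cannot inflate the true-negative count.
#'
#' @param text the record text
#' @param gold,predicted annotation data.frames (disjoint, in-bounds)
#' @param exclude_punctuation drop punctuation-only tokens from scoring
#' @return data.frame with `start`, `end`, `surface`, `gold`, `pred`
#' @export
align_tokens <- function(text, gold, predicted, exclude_punctuation = TRUE) {
  for (ann in list(gold, predicted)) {
    if (nrow(ann) && (any(ann$start < 0L) || any(ann$end > nchar(text)))) {
      stop("annotation out of text bounds")
    }
  }
  tok <- tokenize(text)
  if (exclude_punctuation) tok <- tok[tok$is_word, , drop = FALSE]
  if (nrow(tok) == 0L) {
    return(data.frame(start = integer(), end = integer(), surface = character(),
                      gold = logical(), pred = logical(), stringsAsFactors = FALSE))
  }
  tok$gold <- span_overlaps_any(tok$start, tok$end, gold)
  tok$pred <- span_overlaps_any(tok$start, tok$end, predicted)
  rownames(tok) <- NULL
  tok[, c("start", "end", "surface", "gold", "pred")]
}

#' Confusion counts from token label pairs
#'
#' @param pairs data.frame with logical columns `gold` and `pred`
#' @return named integer vector `tp`, `fp`, `fn`, `tn`; the four sum to the
#'   number of scored tokens
#' @export
confusion <- function(pairs) {
  g <- pairs$gold; p <- pairs$pred
  c(tp = sum(g & p), fp = sum(!g & p), fn = sum(g & !p), tn = sum(!g & !p))
}

#' F-measure from precision and recall
#'
#' `F = 2 * P * R / (P + R)`, defined as 0 when both are 0.
#'
#' @param precision,recall proportions in `[0, 1]`
#' @return F-measure (vectorized)
#' @export
f_from_pr <- function(precision, recall) {
  ifelse(is.na(precision) | is.na(recall), NA_real_,
         ifelse(precision + recall > 0,
                2 * precision * recall / (precision + recall), 0))
}

#' The five performance measures from confusion counts
#'
#' Sensitivity/recall = tp/(tp+fn); specificity = tn/(tn+fp); precision =
#' tp/(tp+fp); accuracy = (tp+tn)/total; F-measure = 2PR/(P+R). Ratios with a
#' zero denominator are reported as `NA` (not applicable), never as 0.
#'
#' @param counts named vector from [confusion()] (or a list with tp/fp/fn/tn)
#' @param per_category optional named list of per-category counts, echoed
#'   into the report with derived measures
#' @return object of class `MetricsReport`
#' @export
compute_metrics <- function(counts, per_category = NULL) {
  counts <- unlist(counts)[c("tp", "fp", "fn", "tn")]
  stopifnot(!any(is.na(counts)), all(counts >= 0))
  total <- sum(counts)
  if (total == 0) stop("no scored tokens: all confusion counts are zero")
  rat <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- rat(counts["tp"], counts["tp"] + counts["fn"])
  spec <- rat(counts["tn"], counts["tn"] + counts["fp"])
  prec <- rat(counts["tp"], counts["tp"] + counts["fp"])
  acc <- (counts["tp"] + counts["tn"]) / total
  rep <- list(counts = counts,
              sensitivity = unname(sens), specificity = unname(spec),
              precision = unname(prec), accuracy = unname(acc),
              f_measure = unname(f_from_pr(prec, sens)))
  if (!is.null(per_category)) {
    rep$per_category <- lapply(per_category, function(ct) {
      ct <- unlist(ct)[c("tp", "fp", "fn", "tn")]
      list(counts = ct,
           sensitivity = unname(rat(ct["tp"], ct["tp"] + ct["fn"])),
           precision = unname(rat(ct["tp"], ct["tp"] + ct["fp"])))
    })
  }
  structure(rep, class = "MetricsReport")
}

#' @export
print.MetricsReport <- function(x, ...) {
  cat(sprintf(paste0("token-level metrics (tp=%d fp=%d fn=%d tn=%d)\n",
                     "  sensitivity/recall %.3f  specificity %.3f\n",
                     "  precision %.3f  accuracy %.3f  F-measure %.3f\n"),
              x$counts["tp"], x$counts["fp"], x$counts["fn"], x$counts["tn"],
              x$sensitivity, x$specificity, x$precision, x$accuracy,
              x$f_measure))
  invisible(x)
}

#' False-positive / false-negative error report
#'
#' Lists every FP and FN token with its offsets, a +/- 5-token context
#' window, and (for FPs) the producing rule, grouped by surface and sorted by
#' frequency so recurring errors surface first.
#'
#' @param text record text
#' @param gold,predicted annotation data.frames
#' @return list with data.frames `fp` and `fn` (surface, count, contexts,
#'   and for fp the rule ids)
#' @export
error_report <- function(text, gold, predicted) {
  al <- align_tokens(text, gold, predicted)
  tok_context <- function(i) {
    lo <- max(1L, i - 5L); hi <- min(nrow(al), i + 5L)
    paste(al$surface[lo:hi], collapse = " ")
  }
  build <- function(idx, with_rule = FALSE) {
    if (!length(idx)) {
      out <- data.frame(surface = character(), count = integer(),
                        offsets = character(), contexts = character(),
                        stringsAsFactors = FALSE)
      if (with_rule) out$rule_ids <- character()
      return(out)
    }
    sur <- cf(al$surface[idx])
    grp <- split(idx, sur)
    out <- data.frame(
      surface = names(grp),
      count = lengths(grp),
      offsets = vapply(grp, function(ii)
        paste(al$start[ii], collapse = ","), character(1)),
      contexts = vapply(grp, function(ii)
        paste(vapply(ii, tok_context, character(1)), collapse = " | "),
        character(1)),
      stringsAsFactors = FALSE, row.names = NULL)
    if (with_rule) {
      out$rule_ids <- vapply(grp, function(ii) {
        rules <- unlist(lapply(ii, function(i) {
          hit <- predicted$start < al$end[i] & al$start[i] < predicted$end
          predicted$rule_id[hit]
        }))
        paste(unique(rules), collapse = ",")
      }, character(1))
    }
    out[order(-out$count, out$surface), , drop = FALSE]
  }
  list(fp = build(which(!al$gold & al$pred), with_rule = TRUE),
       fn = build(which(al$gold & !al$pred)))
}

#' Evaluate a corpus against its reference standard
#'
#' Pools token-level confusion counts over all records (micro-average) and
#' reports per-record and per-category breakdowns. Headline matching is
#' category-agnostic: a predicted span of the wrong category still scrubs the
#' PHI. Records missing from `gold` are listed and excluded with a warning.
#'
#' @param records named list of `Record` objects (or plain texts named by
#'   record id)
#' @param gold,predicted named lists of annotation data.frames keyed by
#'   record id
#' @param exclude_punctuation drop punctuation-only tokens from scoring
#' @return list with `metrics` (a `MetricsReport` with per-category
#'   breakdown), `per_record` (data.frame of counts), and `missing` (record
#'   ids excluded)
#' @export
evaluate_corpus <- function(records, gold, predicted,
                            exclude_punctuation = TRUE) {
  ids <- names(records)
  if (is.null(ids)) {
    ids <- vapply(records, function(r) r$record_id, character(1))
    names(records) <- ids
  }
  missing <- setdiff(ids, names(gold))
  if (length(missing)) {
    warning("records without gold annotations excluded: ",
            paste(missing, collapse = ", "))
    ids <- setdiff(ids, missing)
  }
  per <- lapply(ids, function(id) {
    r <- records[[id]]
    text <- if (inherits(r, "Record")) r$text else r
    g <- gold[[id]] %||% empty_annotations()
    p <- predicted[[id]] %||% empty_annotations()
    al <- align_tokens(text, g, p, exclude_punctuation)
    cats <- unique(c(g$category, p$category))
    percat <- lapply(stats::setNames(cats, cats), function(ct) {
      alc <- align_tokens(text, g[g$category == ct, , drop = FALSE],
                          p[p$category == ct, , drop = FALSE],
                          exclude_punctuation)
      confusion(alc)
    })
    list(counts = confusion(al), per_category = percat)
  })
  names(per) <- ids
  pooled <- Reduce(`+`, lapply(per, `[[`, "counts"))
  all_cats <- unique(unlist(lapply(per, function(x) names(x$per_category))))
  cat_pool <- lapply(stats::setNames(all_cats, all_cats), function(ct) {
    Reduce(`+`, c(list(c(tp = 0L, fp = 0L, fn = 0L, tn = 0L)),
                  Filter(Negate(is.null),
                         lapply(per, function(x) x$per_category[[ct]]))))
  })
  per_record <- do.call(rbind, lapply(ids, function(id) {
    data.frame(record_id = id, t(per[[id]]$counts), stringsAsFactors = FALSE)
  }))
  list(metrics = compute_metrics(pooled, per_category = cat_pool),
       per_record = per_record, missing = missing)
}

#' Reported benchmark rows for the Ontario-adapted de-identification system
#'
#' Printed training/validation performance of the rule-based system this
#' package reimplements, on its private primary-care EMR corpora: the
#' original program, four incremental modification stages, the final
#' training run and two validation sets. Percentages as printed; used to
#' check the internal consistency of the F-measure formula.
#'
#' @return data.frame with columns `stage`, `n_records`, `sensitivity_pct`,
#'   `specificity_pct`, `precision_pct`, `accuracy_pct`, `f_measure`
#' @export
deid_benchmark_rows <- function() {
  data.frame(
    stage = c("original", "ontario_lists", "name_lists", "eponyms",
              "nomenclature_protection", "do_not_remove_final",
              "validation_1", "validation_2"),
    n_records = c(500L, 500L, 500L, 500L, 750L, 1000L, 700L, 500L),
    sensitivity_pct = c(83.4, 91.5, 90.9, 90.9, 92.6, 88.3, 86.7, 80.2),
    specificity_pct = c(71.6, 71.0, 71.8, 71.8, 72.8, 91.4, 91.4, 87.7),
    precision_pct = c(71.0, 70.7, 71.5, 71.5, 72.7, 91.3, 91.1, 87.4),
    accuracy_pct = c(77.0, 79.9, 80.1, 80.1, 81.5, 89.9, 89.0, 83.8),
    f_measure = c(0.77, 0.80, 0.80, 0.80, 0.81, 0.90, 0.89, 0.84),
    stringsAsFactors = FALSE
  )
}
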