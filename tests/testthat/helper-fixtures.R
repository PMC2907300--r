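# Shared fixtures, built once per test run. Everything is generated in code
# from fixed seeds; nothing is read from disk except what the package itself
# writes.

fx <- new.env(parent = emptyenv())

fixture_set <- function() {
  if (is.null(fx$set)) {
    fx$gen <- generate_lexicons(seed = 42)
    fx$set <- compile_lexicon_set(fx$gen$manifest)
  }
  fx$set
}

fixture_gen <- function() {
  fixture_set()
  fx$gen
}

# 200-record decoy-free corpus with the default study densities.
fixture_corpus <- function() {
  if (is.null(fx$corp)) {
    fx$corp <- generate_corpus(corpus_spec(n_records = 200L, seed = 11L),
                               fixture_set())
  }
  fx$corp
}

fixture_results <- function() {
  if (is.null(fx$res)) {
    fx$res <- deidentify_corpus(fixture_corpus(), fixture_set(),
                                engine_config(seed = 11L))
  }
  fx$res
}

# 100-record PHI-free, decoy-only corpus.
fixture_decoy_corpus <- function() {
  if (is.null(fx$decoy)) {
    spec <- corpus_spec(n_records = 100L, seed = 5L, decoy_density = 4)
    spec$phi_density[] <- 0
    fx$decoy <- generate_corpus(spec, fixture_set())
  }
  fx$decoy
}

# Token recall of a gold subset (by planting class) against predictions.
planted_recall <- function(corpus, results, classes) {
  tp <- 0L; fn <- 0L
  for (id in names(corpus$records)) {
    gld <- corpus$gold[[id]]
    gld <- gld[gld$rule_id %in% paste0("planted:", classes), , drop = FALSE]
    al <- align_tokens(corpus$records[[id]]$text, gld,
                       results[[id]]$annotations)
    tp <- tp + sum(al$gold & al$pred)
    fn <- fn + sum(al$gold & !al$pred)
  }
  list(tp = tp, fn = fn, recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
}

random_token_text <- function(n_chars, seed) {
  withr::with_seed(seed, {
    chars <- c(letters, LETTERS, 0:9, " ", " ", " ", "\n", ".", ",", "-", "'",
               "(", ")", "/", ":")
    paste(sample(chars, n_chars, replace = TRUE), collapse = "")
  })
}
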