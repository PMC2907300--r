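# Engine configuration: every context heuristic is listed here and can be
# switched off individually, since the qualification rules for ambiguous
# terms are explicit configuration rather than hidden behaviour.

#' Engine configuration
#'
#' @param trigger_titles title words that qualify an adjacent ambiguous name
#'   (matched with or without a trailing period, case-insensitively)
#' @param trigger_relations relationship words that qualify an adjacent
#'   ambiguous name
#' @param street_suffixes street-suffix words eligible for address detection
#' @param location_prepositions prepositions that corroborate an ambiguous
#'   municipality/business mention ("in <Entry>")
#' @param street_number_window word tokens searched backwards for the house
#'   number (see [street_suffix_guard()])
#' @param postal_adjacency_chars maximum character distance between an
#'   ambiguous location mention and a postal code for corroboration
#' @param rule_ambiguous_name_adjacency,rule_ambiguous_name_trigger,rule_ambiguous_location_preposition,rule_ambiguous_location_postal
#'   individual context-rule toggles
#' @param surrogate_mode `"pseudonym"` or `"tag"`
#' @param seed integer seed for surrogate generation
#' @param score_unit scoring unit for evaluation (`"token"`)
#' @param exclude_punctuation exclude punctuation-only tokens from scoring
#' @param log_level one of `"quiet"`, `"info"`
#' @return a validated list of class `engine_config`
#' @export
engine_config <- function(trigger_titles = c("dr", "mr", "mrs", "ms", "prof"),
                          trigger_relations = c("daughter", "son", "mother",
                                                "father", "husband", "wife",
                                                "sister", "brother"),
                          street_suffixes = c("drive", "street", "road",
                                              "avenue", "boulevard",
                                              "crescent", "court", "lane"),
                          location_prepositions = c("at", "in", "of", "near",
                                                    "from"),
                          street_number_window = 3L,
                          postal_adjacency_chars = 30L,
                          rule_ambiguous_name_adjacency = TRUE,
                          rule_ambiguous_name_trigger = TRUE,
                          rule_ambiguous_location_preposition = TRUE,
                          rule_ambiguous_location_postal = TRUE,
                          surrogate_mode = c("pseudonym", "tag"),
                          seed = 1L,
                          score_unit = "token",
                          exclude_punctuation = TRUE,
                          log_level = c("info", "quiet")) {
  cfg <- list(
    trigger_titles = cf(trigger_titles),
    trigger_relations = cf(trigger_relations),
    street_suffixes = cf(street_suffixes),
    location_prepositions = cf(location_prepositions),
    street_number_window = as.integer(street_number_window),
    postal_adjacency_chars = as.integer(postal_adjacency_chars),
    rule_ambiguous_name_adjacency = isTRUE(rule_ambiguous_name_adjacency),
    rule_ambiguous_name_trigger = isTRUE(rule_ambiguous_name_trigger),
    rule_ambiguous_location_preposition = isTRUE(rule_ambiguous_location_preposition),
    rule_ambiguous_location_postal = isTRUE(rule_ambiguous_location_postal),
    surrogate_mode = match.arg(surrogate_mode),
    seed = as.integer(seed),
    score_unit = match.arg(score_unit, "token"),
    exclude_punctuation = isTRUE(exclude_punctuation),
    log_level = match.arg(log_level)
  )
  structure(cfg, class = "engine_config")
}

#' Build an engine_config from a named list, rejecting unknown keys
#'
#' @param x named list (e.g. parsed from a YAML config file)
#' @return an `engine_config`
#' @export
as_engine_config <- function(x = list()) {
  if (inherits(x, "engine_config")) return(x)
  known <- names(formals(engine_config))
  unknown <- setdiff(names(x), known)
  if (length(unknown)) {
    stop("unknown engine_config keys: ", paste(unknown, collapse = ", "))
  }
  do.call(engine_config, x)
}
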