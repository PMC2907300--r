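Package: emrscrub
Title: Rule-Based De-Identification of Primary-Care EMR Free Text
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Lexicon- and pattern-driven detection of personal health
    information (PHI) in primary-care electronic medical record free text,
    adapted to an Ontario context: gazetteer compilation with
    ambiguous/unambiguous/popular precedence rules, regular-expression
    detectors for health card numbers, postal codes, medical record numbers,
    phones and web/email addresses, clinical-content protections (medical
    eponyms, obstetric/spinal/cardiac nomenclature, single-letter acronyms,
    street-suffix and hyphenated-word guards, a do-not-remove override),
    date preservation with structured-field date-of-birth scrubbing,
    category-consistent surrogate (pseudonym) replacement, a token-level
    evaluation harness, and a seeded synthetic-corpus generator with gold
    annotations for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
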