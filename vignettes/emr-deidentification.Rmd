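---
title: "Rule-based de-identification of primary-care EMR free text"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based de-identification of primary-care EMR free text}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emrscrub)
```

## The problem

Free text in primary-care electronic medical records — point-form progress
notes, consultation and referral letters, discharge summaries, diagnostic
reports, and cumulative-patient-profile entries — mixes personal health
information (PHI) with clinically essential content. Research reuse of this
text requires removing the PHI (names, locations, identifier numbers) while
preserving the clinical content, including dates of visits and
hospitalizations, travel and ethnicity mentions, medication names, and the
dense clinical shorthand that a naive scrubber mangles.

`emrscrub` implements a lexicon- and pattern-based detector in the deid
tradition, adapted to an Ontario primary-care context, together with a
surrogate (pseudonym) substitution pass, a token-level evaluation harness,
and a seeded synthetic-corpus generator that stands in for the private
registries and clinical corpora such systems are normally built on.

## The detection model

The engine scans each record line by line (no annotation ever crosses a
newline) and combines four sources of evidence:

1. **Pattern detectors** for structured identifiers:
   - Ontario health card numbers: 10 digits, consecutive or grouped 4-3-3
     with space/hyphen separators, with an optional one- or two-letter
     uppercase version code;
   - Canadian postal codes: letter-digit alternation `A1A 1A1`, inner space
     optional (hyphens are not valid in the format);
   - medical record numbers: standalone 5-9 digit runs;
   - North-American phone shapes, plus bare 7/10-digit runs forced to the
     phone category by a nearby context word (`tel`, `fax`, `pager`,
     `cell`);
   - web/email tokens with a dotted domain.
2. **Dictionary lookups** against compiled lexicons. Unambiguous entries
   (replacement-pool names, most gazetteer entries) are annotated at every
   occurrence. Ambiguous entries — anything that also occurs on another
   list — need corroborating context: for names, adjacency to another
   name-list token or an immediate trigger word (titles `Dr/Mr/Mrs/Ms/Prof`,
   relations `daughter/son/mother/father/husband/wife/sister/brother`); for
   municipalities and businesses, a preceding location preposition
   (`at/in/of/near/from`) or a postal code within 30 characters.
3. **Protections** that veto candidate detections: medical eponyms
   (Parkinson's, Homan's, Apgar, with or without the possessive), obstetric
   `G#P#A#` and spinal/heart-sound runs (`C6C7T1`, `S1S2S4`) that would
   otherwise look like postal codes, single letters followed by punctuation
   (the "S. O. A. P." charting style), hyphenated tokens whose parts are not
   both listed names ("Operative-Smith", "follow-up"), and street-suffix
   words with no house number within the preceding three word tokens
   ("fitness to drive").
4. **The do-not-remove override**, an absolute veto list (countries,
   medications, body parts, common clinical phrases such as "assessment",
   "emergency", and "1 mm ST elevation") that outranks every detection
   decision.

Dates are deliberately preserved: date removal is disabled by design, and
only the date of birth — located through the structured DOB sidecar field,
in padded, unpadded, ISO, and day-first renderings — is scrubbed. Before
scanning, textual month dates are normalized to numeric form
("June 1, 2007" becomes "06/01/2007") so month words are never mistaken for
names; a month word outside a complete date is left alone and flows to the
name logic.

Overlapping candidates are resolved longest-span-first, with ties broken by
category priority (structured number patterns over names over locations)
and then leftmost. The final annotation set is pairwise disjoint, and a scan
is fully deterministic: all randomness in the package lives in the surrogate
generator and the corpus generator, both seeded.

## Lexicon compilation

`compile_lexicon_set()` executes a fixed recipe over one-entry-per-line
source lists named in a YAML manifest:

1. load (trim, case-fold-deduplicate, skip `#` comments);
2. reclassify businesses: pharmacies and insurance companies are dropped;
   radiology, laboratory and physiotherapy entries move to the healthcare
   facilities list, which is grouped by type (hospital, radiology clinic,
   medical laboratory, physiotherapy clinic, other) so surrogates can be
   type-matched;
3. split municipalities and businesses into ambiguous/unambiguous by
   cross-referencing every other list — an entry on two lists is ambiguous
   on both;
4. filter common English words from every list, using the full
   frequency-ordered common-word list, except the unambiguous names list
   which is screened only against the top of that list (`short_common_n`,
   default 1000 — the sources for the two historical lists give no sizes, so
   the short list is realized as a configurable top slice);
5. merge nicknames and provider names into the ambiguous names;
6. apply popular-name precedence: popular names are deleted from the other
   name lists, and names on both the unambiguous and ambiguous lists are
   deleted from the ambiguous list;
7. strip exact do-not-remove entries from every detection lexicon, so the
   compiled set satisfies the invariant that no veto entry can also be a
   detection entry (the engine still applies the veto at scan time, which
   covers possessive forms, multi-word veto phrases, and lexicon sets
   assembled outside the compiler).

Matching is case-insensitive throughout and operates on whole tokens or
whole multi-token phrases, longest phrase first. The set's checksum is a
content digest over sorted case-folded entries, so source-file ordering is
irrelevant and recompilation is reproducible.

Because the popular list's own matching behaviour is not specified by the
historical system's public description, popular names are treated here like
ambiguous names (context-requiring); their documented role — precedence over
the other lists — is implemented exactly.

## Surrogates

`replace_phi()` substitutes each detected span either with a category tag
(`tag` mode) or with a pseudonym (`pseudonym` mode, the default): names are
gender-matched when the record's gender is known, facilities are replaced by
a facility of the same type, identifier numbers keep their digit-grouping
shape with fresh random digits, and postal codes keep their spacing.
Identical surfaces within a record always map to the same surrogate, and
characters outside annotated spans are byte-identical to the input (an edit
list maps original to new offsets). Surrogates are drawn from the detection
lexicons on purpose: a missed piece of PHI is then indistinguishable from a
pseudonym to a reader ("hiding in plain sight"), and re-scanning a
pseudonymized record annotates only surrogate positions. Both tag and
pseudonym modes are provided because the historical deployment is described
with tags in one place and pseudonyms in another; pseudonym is the default
as the mode used on the production data flow.

`initial_name_removal()` reproduces the clinic-side first pass: every
occurrence of the structured patient and provider names is replaced with a
seeded, gender-matched fake name before anything else happens. The
evaluation pipeline does not re-run this pass; generated records emulate
post-extraction data in which patient and provider structured names are
already drawn from the replacement pool (which is exactly why those names
sit on the unambiguous list).

## Evaluation

Scoring is token-level with any-overlap credit: a token is gold-positive if
any gold span overlaps it and predicted-positive if any predicted span
overlaps it. The public description of the historical system never states
its scoring unit; the token is the finest testable granularity and is the
convention of the original deid evaluation, so it is the default here.
Punctuation-only tokens are excluded from scoring so that true negatives are
not inflated; both choices are arguments (`exclude_punctuation`,
`score_unit`). Headline metrics are category-agnostic (a span scrubbed under
the wrong category is still scrubbed); per-category breakdowns are reported
separately. Corpus metrics are micro-averaged (pooled counts). Ratios with
zero denominators are reported as `NA`, never as 0; the F-measure is
`2PR/(P+R)`, defined as 0 when both P and R are 0.

## The synthetic corpus

`generate_lexicons()` and `generate_corpus()` produce everything the
pipeline consumes. Gazetteer entries are built from syllables so they cannot
collide with the clinical filler vocabulary except where collisions are
planted and logged: municipality/surname and business/municipality overlaps
(which compilation must route to the ambiguous lists), name/common-word
overlaps (which compilation must remove), pharmacy/insurance businesses
(dropped), clinic-type businesses (moved to facilities), and do-not-remove
exemplars planted on a detection list (stripped).

Records are template-filled per note type with recorded offsets for every
planted PHI mention and decoy. Defaults mirror the study setting
qualitatively: six note types with a fixed mix, roughly 10-20 PHI mentions
in a letter-type note and 0-5 in a progress note, all three health-card
format variants, DOB in padded/unpadded/ISO renderings, family-member names
behind relation triggers, and an `ambiguity_rate` (default 0.6) controlling
how many extra name mentions come from the ambiguous lists. PHI-bearing
records use numeric dates only, so month normalization is the identity on
them and gold offsets remain valid for the scanned text; month-word dates
appear only in PHI-free decoy records, where there are no gold offsets to
misalign. Decoy snippets cover every protection: eponyms, `G2P1A1`,
`C6C7T1`, `S1S2S4`, "fitness to drive", single-letter charting, month-word
dates, and do-not-remove exemplars.

What passing on this corpus shows — and what it does not: the generator
plants only surfaces the compiled lexicons contain and contexts the engine's
rules recognize, so planted-truth recall of pattern-category and
unambiguous-lexicon PHI is 100% *by construction*, and decoy precision
checks exactly the protections listed above. Real clinical text contains
misspellings, OCR artifacts, names absent from every list, and contexts
outside the trigger vocabulary; performance there is an empirical question
this corpus cannot answer (the published benchmark numbers for the system
this package reimplements are in `deid_benchmark_rows()`).

## Numerical and design choices

- Offsets are 0-based half-open everywhere, including the standoff TSV
  dialect (`record_id  start  end  category  rule_id  surface`).
- Overlap precedence, trigger vocabularies, street-suffix set, the
  number-window (3 word tokens), and the postal-adjacency distance (30
  characters) are all `engine_config()` arguments; unknown keys are
  rejected.
- Health-card version codes are restricted to uppercase letters so that a
  lowercase word following ten digits is read as prose.
- MRN runs must be delimiter-separated and never part of a decimal number,
  so lab values like `12345.6` are untouched.
- Calendar validity is enforced for date mentions (`06/31/2007` is not a
  date); two-digit years are out of scope.
- Numeric DOB search matches both the month-first and day-first readings —
  conservative over-scrubbing of an ambiguous DOB beats leaking it.
- Test and acceptance corpora use 200 records for recall checks, 100 for
  decoy precision and date preservation, and 50 for the end-to-end
  determinism chain; these sizes exercise every template and decoy branch
  many times over while keeping the suite quick to run.

## Known limitations

- The bundled lists are synthetic stand-ins; no real provincial registry,
  medical directory, drug formulary or body-part classification ships with
  the package, only their file shapes.
- Single-locale: Ontario identifier formats and North-American phone
  shapes; no US SSN/zip handling.
- No machine-learning fallback for names outside the lexicons — by design,
  matching the lexicon-and-pattern adaptation path.
- Date shifting/jittering is a non-goal: dates are preserved for
  administrative linkage, not perturbed.
- Two-digit years and OCR-corrupted text are out of scope.
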