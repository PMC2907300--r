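# emrscrub

Rule-based de-identification of primary-care EMR free text, for researchers
who need to strip personal health information (PHI) from clinical notes —
progress notes, consult and referral letters, discharge summaries,
diagnostic reports, cumulative-patient-profile entries — **without
destroying clinical content**. The detector is a lexicon-and-pattern system
in the *deid* tradition, adapted to an Ontario context: gazetteer lookups
with ambiguous/unambiguous/popular precedence, regular-expression detectors
for Ontario identifiers, context heuristics, clinical-content protections,
and an overriding do-not-remove list. Detected PHI is replaced by
category-consistent pseudonyms so that anything the detector misses hides in
plain sight among the surrogates.

## What it detects and what it protects

Detected categories: patient/provider names, healthcare facilities, street
addresses, municipalities, businesses, health card numbers (10 digits,
optionally grouped 4-3-3, optional 1-2 letter version code), postal codes
(`A1A 1A1`), medical record numbers (5-9 digit runs), phone numbers,
web/email addresses, and the date of birth located via the structured DOB
field.

Protected content: every other calendar date (visit and hospitalization
dates carry clinical meaning and are preserved byte-for-byte), medical
eponyms (Parkinson's, Homan's, Apgar, ...), obstetric `G2P1A1` and
spinal/heart-sound runs (`C6C7T1`, `S1S2S4`) that would otherwise look like
postal codes, single letters followed by punctuation ("S. O. A. P."),
hyphenated non-names ("Operative-Smith", "follow-up"), street-suffix words
with no house number ("fitness to drive"), and an explicit do-not-remove
list ("assessment", "emergency", "1 mm ST elevation", countries,
medications, body parts) that overrides every detection decision.

Evaluation is token-level: sensitivity/recall, specificity, precision,
accuracy, and F-measure = 2PR/(P+R), micro-averaged over a corpus against
gold standoff annotations, with FP/FN error reports grouped by recurring
surface.

## Worked example

Everything below is generated — the package ships a seeded synthetic-lexicon
and synthetic-corpus generator standing in for the private registries and
clinical corpora such systems are normally built from.

```r
library(emrscrub)

gen    <- generate_lexicons(seed = 42)           # synthetic source lists
lexset <- compile_lexicon_set(gen$manifest)      # precedence + filtering rules
corp   <- generate_corpus(corpus_spec(n_records = 5, seed = 7), lexset)

rec <- corp$records[["rec0002"]]                 # a consult letter
res <- deidentify_record(rec, lexset, engine_config(seed = 7))
res$annotations[, c("category", "rule_id", "surface")]
```

```
                category                      rule_id               surface
1               facility                 lex:facility Vossab Imaging Centre
2                 street           ctx:street_address      611 Osthav Drive
3           municipality lex:municipality_unambiguous                Sollod
4            postal_code              pat:postal_code               E5E 9R7
5           phone_number             pat:phone_shaped        (287) 753-0661
6          provider_name             ctx:name_context                Sablod
7           patient_name         lex:name_unambiguous         Tekmur Gardra
8     health_card_number                pat:hcn_plain            1890788537
9  medical_record_number                      pat:mrn               1146131
10         date_of_birth           ctx:structured_dob            03/08/1962
11         provider_name             ctx:name_context                   Tek
```

Each `rule_id` names the producing rule: `pat:*` are pattern detectors,
`lex:*` dictionary lookups, `ctx:*` context rules (e.g. the street rule that
requires a house number before a street-suffix word, or the trigger-word
rule that let "Dr." qualify the ambiguous name "Sablod"). The pseudonymized
output keeps every non-PHI byte — note the preserved visit date, the
type-matched facility surrogate (an imaging centre becomes a radiology
clinic), the shape-preserving identifier numbers, and the scrubbed DOB:

```
Quintor Radiology
619 Tektra Drive
Tekost, Ontario  R7H 5R7
Tel: (923) 715-5435
01/17/2005

Dear Dr. Bexzan:
Re: Patient: Malyor Malven  HCN 3577038247  MRN 8457814
DOB: 11/28/1937
...
```

Scoring the whole 5-record corpus against its gold annotations:

```r
ev <- evaluate_predictions(corp, deidentify_corpus(corp, lexset, engine_config(seed = 7)))
ev$metrics
#> token-level metrics (tp=44 fp=0 fn=0 tn=160)
#>   sensitivity/recall 1.000  specificity 1.000
#>   precision 1.000  accuracy 1.000  F-measure 1.000
```

Perfect scores here reflect the synthetic corpus, which only plants surfaces
the compiled lexicons contain — see the vignette
(`vignettes/emr-deidentification.Rmd`) for what that does and does not show
about real clinical text. `deid_benchmark_rows()` carries the published
training/validation figures of the system this package reimplements.

## Command line

A thin Rscript wrapper exposes the four workflows:

```sh
Rscript inst/cli/emrscrub.R compile-lexicons --manifest lists/manifest.yaml --out lex/
Rscript inst/cli/emrscrub.R generate-corpus  --lexicons lex/ --out corpus/ --n 50 --seed 3
Rscript inst/cli/emrscrub.R deidentify       --in corpus/ --lexicons lex/ --out deid/ --seed 3
Rscript inst/cli/emrscrub.R evaluate         --in corpus/ --pred deid/ --out report.json
```

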