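---
title: "Points-based fraud screening for incentivized online surveys: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Points-based fraud screening: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surveyguard)
```

## The problem

Incentivized web surveys attract two kinds of illegitimate respondents:
humans outside the target population who complete surveys solely for the
payment ("professional survey takers"), and software that auto-completes
forms in bulk ("bots"). Both can swamp a study within hours of launch —
attacks of thousands of screener attempts against an advertising reach of a
hundred people are realistic — and both undermine data integrity if their
records enter analysis. surveyguard implements the data-side defenses: a
validated two-stage eligibility screen, per-indicator fraud detectors, a
points-based classifier, and a labelled cohort simulator for validating the
whole pipeline without touching real respondent data.

## The scoring model

Each record is evaluated against a fixed set of indicators. Every indicator
that fires contributes a point value reflecting how strongly it suggests
fraud, each indicator counts at most once per record, and a record whose
total reaches **2 points** is labelled *fraudulent*:

| points | rule id | indicator |
|---|---|---|
| 1 | `short_completion` | completion time infeasibly short (< 8 min; valid times run 8–20 min, median 17) |
| 1 | `geo_simultaneous` | same county + zip as another record submitted within 60 s |
| 1 | `cluster` | member of a group of 3+ records with identical/similar item answers |
| 1 | `odd_email` | unusual email format (digit runs, consonant runs, doubled-letter name misspellings) |
| 1 | `speedbump` | incorrect speed-bump answer |
| 1 | `inactive_source` | recruitment source inactive on the submission date, or never used at all |
| 1 | `dup_ip` | hashed IP address shared with another record |
| 1 | `wave` | submitted in regularly spaced batches (e.g. 3 responses every 5 min) |
| 2 | `cross_form` | screener/survey or within-form inconsistency (county, zip, duplicated questions, age vs grade, nonexistent zip) |
| 2 | `dup_text` | open-ended text identical (or near-identical) to another respondent's |
| 2 | `tz_disparity` | client clock more than 60 min from the server clock |
| 2 | `dup_contact` | email/phone/postal address already reported by another respondent |

So one strong (2-point) indicator or any two weak ones suffice. The cutoff
and the per-rule points are overridable through `scoring_policy()` and the
`[scoring]` config section, but the defaults above are the calibrated
operating point: they were designed so that verified known-good responses
score zero, which is what the packaged clean fixture regression asserts.

The honeypot — a field invisible to human respondents — is deliberately *not*
a scored indicator (it contributes 0 points in reports). It is instead an
immediate rejection at the screener stage: any non-blank value can only come
from automation.

## The two-stage screen

`screen_eligibility()` validates public screener submissions before a survey
link is ever issued. A record is **ineligible** when the marked county is not
in the eligible set, more than one county is marked, the zip code is unknown
or maps to a different county than the one marked, the CAPTCHA (modelled as a
boolean pass flag) failed, or a speed bump was answered incorrectly. It is
**barred** — the stronger outcome, taking precedence — when the
client/server timestamp disparity exceeds the time-zone threshold or the
honeypot was answered: these are automation signatures rather than mere
eligibility failures. The reasons vector always lists *every* failed gate, so
review staff see the whole picture, not just the first failure.

Requiring the zip code to agree with the marked county is what defeats
brute-force eligibility probing: an attacker cycling answer combinations must
hit a consistent (county, zip) pair, not merely an eligible county.
`generate_bruteforce_probe_stream()` emulates exactly this attack for
testing.

## Detector parameters

All thresholds live in `detector_params()` and the `[detectors]` config
section:

* `short_completion_minutes = 8` (minutes). Strictly-below comparison: 8.0
  does not fire, 7.999 does. The bound comes from instrument pre-testing
  (valid range 8–20 min).
* `tz_disparity_minutes = 60` (minutes). Strictly-above comparison: a
  60-minute disparity does not fire, 60.01 does. Records whose timestamps
  lack an explicit UTC offset are flagged "no timestamp info" and excluded
  from disparity logic rather than guessed at.
* `batch_window_seconds = 60` (seconds): consecutive submissions closer than
  this join one batch in the wave detector.
* `min_cluster_size = 3`: two identical responses are plausible coincidence;
  three or more are not.
* `similarity_threshold = 0.90`: fraction of item answers that must agree for
  two records to count as "similar". Item-agreement fraction with
  single-linkage grouping was chosen over fancier distances because it is
  simple, auditable, and checkable by brute force in tests.
* `wave_cv_tolerance = 0.10`: "regular intervals" is operationalised as the
  coefficient of variation of inter-batch gaps, computed over batches with at
  least two members, requiring at least three such batches. A CV test
  captures "3 responses every 5 minutes" exactly (CV = 0) while tolerating
  small jitter, and cannot fire on a single burst.
* `simultaneous_window_seconds = 60`: "simultaneous" for the county+zip match
  rule. Chosen to match the batch window; both are configurable.
* `email_digit_run = 4`: a local part containing 4+ consecutive digits is
  machine-like. Year suffixes (2 digits, e.g. `jane.smith85`) stay safe.
* `neardup_text_threshold = 0.90`: normalized edit similarity
  (1 − Levenshtein distance / longer length) at which two open-text answers
  count as near-duplicates. Texts under 10 characters after normalization are
  exempt — short pleasantries ("thanks!") collide innocently.

### The unusual-email heuristics

Three individually sufficient criteria, each mirroring a distinct
machine-generation pattern: (a) a digit run of 4+ in the local part
(`asfs241421@…`); (b) a consonant run of 5+ after removing digits (keyboard
mash); (c) an alphabetic token at edit distance 1–2 from a given-name lexicon
entry *that introduces a doubled letter the name does not have*
(`hannaah`, `smiith`). The doubled-letter requirement is what keeps
legitimately doubled names (hannah, emma) from firing against close lexicon
neighbours. The shipped lexicon (141 common given names) was screened so that
no lexicon name or simulator surname triggers criterion (c) against any
other, and the packaged list of 50 plausible addresses
(`extdata/legit_emails.txt`) produces zero firings at the default thresholds
— that calibration is asserted in the test suite.

### Age–grade plausibility

Only one anchor is given by the methodology this implements (5 years old in
8th grade is inconsistent), so the plausible band had to be chosen here:
for grade *g* (kindergarten = 0) the plausible age is *g*+4 through *g*+8
years inclusive. That spans typical US enrollment ages plus one retention
year, classifies (5, grade 8) as inconsistent, and accepts (13, grade 8).

## Degenerate inputs and tie-breaks

Malformed zips and timestamps are loaded and *flagged*, never rejected — a
mangled field is evidence. Empty IP hashes and contact fields never match
each other. A missing completion time or timestamp makes the corresponding
rule report "missing data" without firing. Duplicate rule results for one
record are an error (an upstream invariant breach), not silently collapsed.
An indicator observed on both a respondent's screener and survey counts once
per rule — the survey record is the unit of scoring. Cluster grouping uses
connected components of the at-or-above-threshold graph (single linkage), so
group membership is order-independent; all population detectors are
permutation-invariant, which the property tests assert.

## The simulator

`generate_cohort()` produces paired screener/survey tables with ground-truth
labels under a three-archetype mixture (default 0.7 / 0.1 / 0.2
legitimate / professional / bot):

* **Legitimate** records are internally consistent (county matches zip, age
  matches grade, duplicated questions agree), with unique contact details and
  IPs, personal-looking emails built from the shipped name lexicon, unique
  free text assembled from a topic vocabulary, zero client/server disparity,
  and daytime arrivals spaced at least two minutes apart.
* **Professional** records keep human-plausible timing and answers but share
  contact details in pairs and draw IPs from a pool of two — the archetype is
  defined behaviourally: a human who participates repeatedly.
* **Bot** records arrive in batches of 3 every 5 minutes starting in the
  middle of the night, finish in 1–5 minutes, carry digit-suffixed random
  emails, identical item answers within each wave, one of two copied
  open-text strings, a single shared county+zip pair, pooled IPs, wrong
  speed-bump answers, and a client clock 12 hours off. A configurable
  fraction (default 0.2) spoof their clock to match the server; by
  construction they lose exactly the 2-point time-zone indicator and nothing
  else, which is how the suite tests that detection degrades gracefully
  rather than collapsing.

### Completion-time calibration

The legitimate completion-time target is minimum 8, maximum 20, median 17
minutes. No triangular distribution on [8, 20] can attain a median of 17
(its largest possible median, at mode 20, is 8 + √72 ≈ 16.49), so the
sampler uses a scaled Beta(4, *b*) on [8, 20] with *b* solved numerically so
the distribution median is exactly 17. With 10,000 draws the sample median
lands within a few hundredths of a minute of 17.

### What the simulator does and does not show

The generator is adversarial-by-construction: every bot is built to trip
multiple rules and every legitimate record to trip none, so perfect
sensitivity and a zero false-positive rate on synthetic cohorts (asserted
across 20 seeds at n = 300) validate the *plumbing* — thresholds, strictness,
aggregation, invariants — not real-world operating characteristics. Real
data contain legitimate households sharing an IP, honest typos in zips,
respondents with unusual-but-real emails, and fraudsters with humanised
timing; on such data the points system is a triage aid for human review, not
a verdict. Clock-spoofing fraudsters are acknowledged as undetectable by the
disparity rule, VPN/proxy detection is out of scope, and remuneration
decisions should never be automated.

### Validation problem sizes

The suite validates the pipeline at cohort sizes of 200–300 records
(20 seeds for the recovery property) and calibrates completion times at
n = 10,000; these sizes give stable statistics while keeping the full suite
in the minutes range on a single CPU.

## Configuration and interfaces

All I/O is RFC-4180-style CSV with a header row (delimiter configurable).
One YAML file binds the column mapping, eligible counties, reference-table
paths, detector thresholds, scoring overrides, simulator settings, and log
level; `inst/extdata/config.yaml` is a working example. The three command
wrappers (`cmd_screen()`, `cmd_score()`, `cmd_simulate()`) and the thin
Rscript in `inst/cli/` write a small key-value manifest (command, inputs,
seed, version, timestamp) alongside every output for reproducibility.

## Known limitations

* The disparity rule compares parsed instants; a respondent whose browser
  reports a correct offset for a non-target time zone is caught, but one who
  spoofs the clock is not.
* Near-duplicate text detection is O(n²) in unique texts; cohorts in the
  tens of thousands would need blocking before the pairwise pass.
* The email misspelling heuristic is lexicon-bound: names absent from the
  lexicon cannot be flagged as misspelled.
* The screener-stage CAPTCHA is modelled as a boolean pass flag; resistance
  of the CAPTCHA itself is out of scope.
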