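---
title: "Harmonizing free-text medication records: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonizing free-text medication records: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Self-reported medication lists collected as free text mix several kinds
of noise on top of the drug name itself: misspellings, brand names
standing in for generics, dose and frequency fragments ("10 mg",
"2 tablets daily"), combination products joined by hyphens or slashes,
arbitrary case, and over-the-counter supplements that do not belong in a
prescription-medication analysis at all. The analysis target, by
contrast, is a clean three-way structure: a canonical generic name per
record, a therapeutic class per name, and a participant-by-visit binary
exposure matrix per class.

`rxharmonize` models curation as a staged funnel with strict
accounting. Each phase consists of ordered processes; each process
partitions its input into *correct* (newly resolved), *ambiguous*
(flagged and frozen for expert review — this bucket also carries
borderline-score holds), and *unmatched* (passed to the next process).
The three must always sum to the process input; the report builder
refuses to tabulate counts that leak or duplicate entries. Nothing is
ever silently dropped: entries that survive every automated process land
in explicit queues, and an append-only audit log records every state
transition so that a verifier (`verify_audit_chain()`) can re-derive the
final status of every record from its transition history.

### Phase 1 — name standardization

After normalization (lowercasing; punctuation stripped except decimal
points and hyphens inside dose tokens; slash- and hyphen-joined
combinations canonicalized to a single hyphen; short hyphen fragments
such as "co-codamol" rejoined), entries pass through four automated
processes:

1. **Absolute match** — exact equality of the dose-stripped name
   against the lexicon of generic and trade names. Combination products
   are matched by their primary (first-listed) active ingredient only.
   An entry whose tokens hit two or more distinct canonical drugs is
   ambiguous; a brand name alongside its own generic is not, since both
   witness the same canonical.
2. **Fuzzy match** — best lexicon candidate under the configured string
   metric, accepted at or above the threshold (default 0.90) when the
   top candidate is unique. Scores in the borderline band (default
   [0.85, 0.90)) are held for review rather than auto-accepted or
   discarded; top-score ties at threshold are ambiguous.
3. **Dictionary absolute** and 4. **dictionary fuzzy** — the same two
   operations against an expert-curated variant dictionary that grows
   over time: every accepted expert decision whose surface form differs
   from its canonical is appended, so adjudication cost is paid once per
   variant, not once per record.

Queues are frozen: an entry flagged ambiguous or borderline at stage
*k* does not continue to stage *k*+1. This is deliberate — downstream
stages are weaker evidence, and silently resolving a flagged entry
would undercut the audit trail's claim that every automated match met
its stage's acceptance rule.

### Phase 2 — therapeutic classes

Unique standardized names (never raw records) are classified by exact
match to generic monograph titles, then trade-name resolution, then
fuzzy match against clinical-drug-form strings with dose-form words
stripped. Assignments accumulate in a persistent classification map; a
known name is never recomputed, which both saves work and guarantees
that one name cannot drift between classes across runs. A trade name
resolving to multiple generics with different classes, or a fuzzy tie,
goes to the expert queue. Class numbers form a four-level hierarchy in
which each level is a prefix of the next, so level-2/3 class texts are
looked up from the class records of the prefix numbers.

### Phase 3 — exposure matrix

Long (participant, visit, name, class) rows become a wide binary
matrix: a cell is 1 iff at least one record witnesses that
participant-visit-class. Records whose name has no class assignment are
routed to an `unclassified` side table. An optional merge map
consolidates pharmacologically similar classes (applied as a transitive
closure, with cycle detection), the `level` argument rolls columns up
the hierarchy by prefix, and an optional visit roster materializes
all-zero rows — without a roster, a missing row cannot be told apart
from a visit with no eligible medications, so true zeros are only
claimed when enrollment is declared.

### Phase 4 — QA

`build_report()` produces the stage-accounting table with one row per
process and each process's share of the phase total; `qa_sample()`
draws seeded review samples with a dual-verification flag on matches
from the fuzzy and expert methods; `write_audit_log()` emits the
JSON-lines audit stream.

## String metrics and the default binding

Two similarity metrics are implemented in-package (they are the
pipeline's core primitives, and their exact conventions matter):

- **Character n-gram Jaccard** (default n = 2): the ratio of shared to
  total *distinct* n-grams, without padding; strings shorter than n fall
  back to exact equality (1 or 0).
- **Normalized Levenshtein similarity**: 1 − d/max(|a|, |b|) with
  unit-cost dynamic-programming edit distance; two empty strings have
  similarity 1.

The fuzzy stages bind to a configurable `fuzzy_metric`, and the default
is **Levenshtein**. The reason is arithmetic, not taste. The dominant
error mode in self-reported names is the single-character typo. One
edit on a 12-character name leaves Levenshtein similarity at 11/12 ≈
0.917, comfortably above a 0.90 threshold; but the same edit disturbs
up to three of the string's bigrams, leaving bigram-Jaccard similarity
around 0.67–0.75 — far below 0.90. A bigram-Jaccard binding at 0.90
therefore recovers almost no misspellings (consistent with reported
stage yields in which the n-gram fuzzy stage resolved a negligible
share and the expert dictionary had to absorb the rest), whereas the
Levenshtein binding resolves exactly the one-edit population the
threshold is meant to capture. Both metrics are retained because the
Jaccard form is cheap, order-insensitive, and useful for candidate
generation and diagnostics.

Threshold comparisons use an epsilon of 1e-12 and are inclusive, so a
score of exactly 0.90 (e.g. one edit on a 10-character name, 9/10)
passes a 0.90 threshold despite floating-point representation. Ties are
never broken silently: a non-unique top score is an ambiguity. Candidate
rankings sort by descending score with the candidate string as a
deterministic tiebreaker, so results are byte-stable across runs.

`calibrate_threshold()` supports choosing the threshold empirically: it
draws seeded samples from similarity bands (default [0.86, 0.90),
[0.90, 0.95), [0.95, 1.00]), computes per-band precision from expert
accept/reject labels, and recommends the lowest band edge above which
every populated band meets the precision target.

## Numerical conventions

- Percentages are 100 × correct / phase-total, rounded **half-up** to
  one decimal (`round_half_up()`), not banker's rounding — this is the
  convention under which 14,273 of 16,902 prints as 84.4 and 439 of 477
  prints as 92.0. Audit records carry scores on the same percentage
  scale.
- The phase total defaults to the input of the phase's first process,
  so later processes report their share of the *phase*, not of their
  own (shrinking) input.
- All sampling (QA draws, calibration, the generator) goes through
  `withr::with_seed`, leaving the caller's RNG state untouched; the
  generator derives per-stream seeds so reference and corpus streams
  are independent but jointly reproducible.

## The synthetic generator: realism and limits

`generator_config()` defaults encode the emulated study conditions:
50 participants × 4 visits × 5 entries = 1,000 records; 17% of entries
misspelled with at most one edit; 25% reported by brand name; 30%
carrying dose/frequency suffixes; 5% combination products; 10%
OTC/supplement distractors; 30% case noise. Names are pronounceable
(three consonant-vowel syllables plus a common drug-name suffix, always
at least 10 characters) and rejection-sampled so that every pair of
reference names — generic or trade — is at least 4 edits apart.

That separation is the lever that makes ground-truth evaluation sharp:
a one-edit misspelling of a 10+ character name scores at least 0.90
against its source but can score at most 1 − 3/13 ≈ 0.77 against any
other reference name, so under the default configuration fuzzy matching
is provably unable to defect to the wrong drug, and measured precision
reflects the pipeline rather than luck. The generator's limits are the
mirror image of this cleanliness: real reference sets contain
near-neighbor names (e.g. distinct drugs two edits apart), real typists
make multi-edit and phonetic errors, and real OTC mentions are more
varied than the fixed distractor list. The configuration exposes all of
these rates — raising `max_edits_per_name` or the misspelling rate
produces corpora that genuinely exercise the expert queue and the
dictionary-growth loop, which is how the replay tests construct their
scenarios.

One realistic artifact is worth knowing about: a distractor like
"omega 3 1000 iu" can survive a token-level exclusion filter because
"3" parses as a dose token. Such entries end up in the unmatched queue
rather than the excluded set — the safe place for them, since expert
review sees everything the automated stages could not place.

## Design decisions

- **Both metrics authored in-package.** The DP edit distance and the
  set-based Jaccard are small, and their conventions (normalization
  denominator, no-padding n-grams, short-string fallback, empty-string
  cases) are load-bearing; `utils::adist` is used only as an
  independent cross-check in the test suite.
- **Tabular IO through readr/jsonlite.** All artifacts are plain CSV or
  JSON-lines, append-friendly and diffable; columns are read as
  character and coerced deliberately.
- **Errors are classed.** Every failure mode has a condition class
  (`rxh_schema_error`, `rxh_integrity_error`, `rxh_conflict_error`, …)
  so callers and the CLI can distinguish a malformed file from a
  violated invariant, and messages name the offending column, key, or
  stage.
- **The CLI is a thin veneer.** `inst/scripts/rxharmonize` parses
  flags, loads the documented artifacts, calls the same exported
  functions, and writes a manifest per run; logs go to stderr, machine
  output only to files; validation failures exit nonzero with the named
  cause.
- **Problem sizes in the test suite are the package's own choice.**
  Oracle comparisons run exhaustively where an exponential recursion is
  affordable (all pairs to length 3 over a 3-letter alphabet), against
  an external implementation exhaustively to length 4, and on large
  random samples (length ≤ 8, plus 10,000 random Jaccard pairs)
  beyond that.

## Limitations

The package harmonizes names; it does not parse dose into structured
strength/route/frequency fields, reconcile duplicate reports of the
same drug within a visit beyond the binary indicator, or connect to
external terminology services. The classification stage assumes the
reference tables are internally consistent (and verifies their
referential integrity at load time); it does not attempt to adjudicate
conflicting class assignments beyond routing them to expert review.
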