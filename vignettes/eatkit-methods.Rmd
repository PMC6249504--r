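---
title: "Curating a food-composition database for a dietary-assessment app"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating a food-composition database for a dietary-assessment app}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eatkit)
```

`eatkit` models the construction of an app-facing food database from a
national food-composition reference, and the app behaviours that database
has to support. This vignette explains the methods: the model behind each
stage, the tunable parameters and why their defaults are what they are,
the numerical choices made where the design was genuinely open, what the
synthetic-fixture generator does and does not emulate, and the known
limitations.

## The data model

A food database is a tibble, one row per food. Generic foods carry an
8-character hierarchical ID whose leading 2/3/5 characters are the major,
sub-major and minor classification codes (the minor category — "apples",
"pome fruit" — is the stratum within which merging is allowed). Each food
has a per-100 g or per-100 mL nutrient panel: energy in kJ plus the
25-nutrient tracked panel returned by `tracked_nutrients()`. The panel
membership is configuration, not code: the reference standard names the
count but not the list, so the default covers macronutrients, fatty-acid
classes, sugars and starch, fibre, headline minerals and vitamins,
cholesterol and moisture, and every similarity and completeness check
reads the same list.

Two representational rules matter downstream:

* **Absent is not zero.** A missing nutrient cell is `NA`. A chain item
  that never declared fibre is not a food with zero fibre; completeness
  checks (`validate_database()`, `drop_incomplete()`) depend on the
  distinction, and the similarity predicate refuses incomplete panels
  rather than guessing.
* **Bases never mix.** Foods measured per 100 g and per 100 mL are never
  compared, merged or converted into each other; whether the published
  pipeline harmonised beverage bases is unknowable from the outside, so
  the toolkit keeps them distinct throughout.

## Removal with an auditable ledger

Rules are an *ordered* list of (reason, matcher) pairs; a food is removed
by the first rule that matches, so a dried legume that is both an
"ingredient" and absent from the consumption survey is counted once, under
`ingredient`. The consumed-ID screen runs after all explicit rules: foods
no survey respondent in the target cohort ate are removed as
`not_consumed_or_undefined`. First-match semantics make the ledger a
partition — every removed food has exactly one reason, and
`kept + removed = original` always holds.

`summarize_ledger()` reports per-reason shares of all removals and the
total's share of the original database, half-even rounded to 2 decimal
places (R's `round()`); tests compare percentages with ±0.005 slack and
accept the per-reason shares summing to 100 ± 0.02 from rounding.

## Merging nutritionally similar foods

The merge criterion is "within ±*t* for energy and all 25 nutrients",
default *t* = 0.10. Two open design points had to be fixed:

* **The denominator.** "Within ±10%" does not say 10% *of what*. The
  toolkit uses the symmetric, division-safe form
  `|a − b| / max(a, b) ≤ t`, with both-zero pairs similar and zero
  against positive dissimilar (their relative difference is 1). The max
  denominator is conservative: it never declares a pair similar that the
  smaller-denominator reading would reject.
* **Non-transitivity.** Pairwise similarity does not chain: A within 10%
  of B and B within 10% of C does not put A within 10% of C. Merging
  connected components would therefore merge pairs that violate the
  criterion. The toolkit instead extracts *cliques* — every pair inside a
  group satisfies the predicate — greedily and deterministically: foods
  sorted by ID, each group seeded by the smallest unassigned ID, then the
  smallest-ID food similar to all current members is added repeatedly.
  Greedy smallest-ID seeding is not maximum-clique optimisation; it is
  chosen for determinism and auditability, and the test suite checks it
  against an independently written brute-force oracle on every fixture.

Merged records average each nutrient arithmetically (unweighted — the
reference gives no consumption weights at this stage), take the smallest
member ID, union the portion options by label, and keep every member's
original name as a synonym. Display names join distinct trailing variety
descriptors when the members share a name stem ("Apple, green" +
"Apple, golden" → "Apple, golden/green", members in ID order); otherwise
a rename-map entry or the smallest-ID member's name is used.

## Chain items

Branded ready-to-eat items carry only the seven nutrients mandatory on an
Australian Nutrition Information Panel. Menus may declare values per 100 g
or per serve — NIPs print both — so each file carries a basis flag and
per-serve values are rescaled by `100 / serve_size`; the conversion
round-trips to within 1e-9 relative error. Label-incomplete items are
dropped (with the missing fields recorded), names get the `", <chain>"`
suffix that `validate_database()` later enforces, and items are filed
under a reserved pseudo major group ("90") with one sub-major per menu
category, since chains have no place in the generic hierarchy. An
`available` flag column stands in for the manual menu-availability review,
which is a human process outside the toolkit.

## Portions

Household measures convert by gram weight when present, else by
volume × density. When a row carries both and they disagree by more than
0.5%, the gram weight wins and the discrepancy is warned about — weights
are measured, densities are often rounded. Category-matched standard sets
add portions like the 285/425/570 mL glass sizes for alcoholic beverages
(configuration with documented defaults; the published examples name the
device, not the sizes). Every food always ends with a `100 g` / `100 mL`
fallback so the amount-and-unit entry path can never dead-end.
`assign_portions()` deduplicates by label and is idempotent.

## Search

Usability testing of food-diary apps repeatedly surfaces the same failure
modes: hyphenated brand names ("Weet-Bix" vs "weetbix"), dropped
apostrophes ("cows milk"), `&` vs "and", colloquial names ("Coke",
"hot chips"), concatenations ("icecream"), and exact phrases not ranked
first. The engine addresses each deterministically:

* `normalize_food_text()` lowercases, deletes apostrophes, expands `&` to
  ` and `, deletes hyphens (joining the fragments), turns other
  punctuation into spaces and collapses whitespace. It is idempotent, and
  is applied identically at index and query time — which is what makes
  spelling-variant invariance a theorem rather than a hope.
* The index stores each food's normalised name, a space-collapsed variant
  (catching "icecream"), its word tokens, and its normalised synonyms;
  colloquial names are curated synonyms, not fuzzy matches. No
  edit-distance matching is on by default: misspellings are handled by
  curated alternative spellings, keeping ranking fully explainable.
* Ranking is tiered: (0) curated keyword shortlists, surfaced when the
  query equals the keyword, in curated order — the primary disambiguation
  device for high-frequency terms like "milk"; (1) exact normalised-name
  matches; (2) foods containing *every* query token as a whole word (AND
  semantics — long lists were the dominant usability complaint, and OR
  would lengthen them), alphabetically; (3) substring matches over names,
  collapsed names and synonyms, alphabetically. Synonyms deliberately
  match at tier 3 only, so a colloquialism never outranks a food actually
  named by the query. Alphabetical order is byte order on the normalised
  name, which is locale-independent.

A food in several tiers keeps its best tier; ties inside a tier break by
food ID. Two identical queries always return identical results.

## Diary and usability scoring

The logging day rolls over at 03:00 local time, not midnight, so
late-evening eating attaches to the day it belongs to; `add_entry()`
rejects entries whose logging day precedes the current one, which is the
whole retrospective-editing defence. The 03:00 instant itself belongs to
the new day (boundary inclusivity is unstated in the source design; this
choice is documented and tested). The store is append-only — accepted
entries are never rewritten — and persists as JSON lines. An entry's
amount is a count of its chosen unit, which structurally prevents the
"600 × 600 mL bottle" class of double-entry error. Manual (free-text)
entries are flagged and `manual_review_queue()` lists them for researcher
follow-up.

SUS scoring is the standard arithmetic: odd items contribute
`score − 1`, even items `5 − score`, sum × 2.5, bounded in [0, 100] with
the all-3 profile scoring exactly 50. The above-average threshold (68) is
configuration. Only the arithmetic is in scope: observed usability scores
are properties of human participants, not of this software.

## The synthetic-fixture generator

Real reference and chain data are licensed and not redistributable, so the
test surface is a generator with a ground-truth manifest. It emulates the
*structure* that the pipeline's correctness depends on: nested
2/3/5-character codes under 8-character IDs, complete 26-value panels with
category-level lognormal baselines, planted mergeable clusters, planted
removal categories with a consistent consumed-ID list, chain menus with
planted label-incomplete items and mixed per-100/per-serve bases,
household measures using both weight paths, rename/keyword maps, diary
streams and SUS responses. Identical seed and parameters regenerate
byte-identical files.

Two constructions make planted-cluster recovery exact rather than merely
likely:

* **Within-cluster spread.** Members of a planted cluster share one base
  profile multiplied, per nutrient, by factors drawn from
  `[1 − s/2, 1 + s/2]` with `s = 0.8 t`. The worst pairwise relative
  deviation is then `s / (1 + s/2)` ≈ 0.077 for `t = 0.10` — inside the
  tolerance *by construction*. (Drawing factors from the wider
  `[1 − s, 1 + s]` would allow pairwise deviations up to
  `2s / (1 + s)` ≈ 0.148, which silently breaks the guarantee; the
  narrower interval is deliberate.)
* **Between-profile separation.** Distinct profiles within a minor
  category sit on a multiplicative ladder (factor 1.6 per slot, ±1%
  jitter), so any two non-cluster foods differ by ≥ 30% in *every*
  nutrient — far beyond 2.5 × tolerance. Recovery of planted clusters is
  therefore a sharp pass/fail property, asserted exactly against the
  manifest over 50 seeded replicates.

What the generator does *not* emulate — and what passing tests therefore
do not show: realistic nutrient magnitudes or correlations between
nutrients (real foods' panels co-vary; fixtures' are independent draws),
realistic name distributions, borderline similarity cases sitting *at*
the tolerance (real minor categories contain near-10% pairs whose
grouping is sensitive to the denominator convention), or the actual
reference's category sizes. Conclusions about recall on real data need
real data.

`paper_scale_profile(n)` returns parameters whose removal-category
proportions follow the published breakdown (608 : 81 : 52 : 25 : 16 : 912
of 5740) scaled to `n` by largest-remainder apportionment — exact at full
scale, within one count per category below it — and a generic/chain split
following the published 64 : 36 composition.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run the merge oracle at
n = 200 foods, conservation at 10 seeds × 120 foods, and cluster recovery
at 50 replicates × 80 foods — sizes at which the brute-force oracle is
exhaustive while the whole suite stays fast; the grouping algorithm
itself is quadratic per stratum and handles full-reference scale.
Percent rounding is half-even to 2 dp; CSV output is byte-deterministic
(fixed column order, rows in byte-order by ID, portions serialised at
full precision with `%.17g`); all sorting is byte-order (`radix`) so
results do not depend on the session locale.

## Known limitations

* The ledger arithmetic of the published pipeline is itself slightly
  tense (its stage totals do not reconcile exactly); the toolkit reports
  its own conservation-consistent counts and never forces a printed
  total.
* Whether "n foods combined" counts members or resulting groups is
  ambiguous in common reporting; `summarize_merges()` reports both.
* Merged display names fall back to the smallest-ID member's name when
  stems differ; a curated rename entry is the intended override.
* The search engine is intentionally non-fuzzy; genuinely novel
  misspellings need a synonym curation pass, mirroring how the deployed
  design handled them.
* Portion labels may not contain `|` or `=` (reserved by the CSV
  serialisation); ingest rejects them rather than escaping.
* Diary timestamps are taken at face value on the participant's local
  clock; timezone changes mid-study are not reconciled.
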