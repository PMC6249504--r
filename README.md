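# eatkit

Tools for building and operating the food-composition database behind a
mobile dietary-assessment app, for nutrition researchers who need their
participants — not trained coders — to find, name and quantify the foods
they eat.

National food-composition references (AUSNUT 2011-13 style: ~5700 foods
with 8-character hierarchical codes and per-100 g panels of energy plus 25
nutrients) are written for analysts, not the public: they carry foods
nobody in a young-adult cohort eats, near-duplicate entries that bloat
search results, long formal names ("Soft drink, lemonade, regular"), and no
branded ready-to-eat chain items at all — the foods that dominate eating
out. `eatkit` implements the curation pipeline that turns such a reference
into an app database, and the app-side logic that database serves:

1. **Reason-coded removal** — ordered rules (ingredients, foods superseded
   by chain data, foods for other populations, supplements, children's
   foods) plus a consumed-ID screen, producing an auditable
   `RemovalLedger` with exact share arithmetic.
2. **Similarity merging** — within a minor category, foods whose energy and
   all 25 tracked nutrients agree within a tolerance *t* (default ±10%)
   under the symmetric predicate `|a − b| / max(a, b) ≤ t` are collapsed
   into cliques (every merged pair satisfies the criterion) and averaged;
   "Apple, green" + "Apple, golden" → "Apple, golden/green".
3. **Chain integration** — branded menus carrying only the seven mandatory
   label nutrients (energy, protein, total/saturated fat, carbohydrate,
   sugars, sodium), per-serve values rescaled to per-100, label-incomplete
   items dropped, names suffixed with the chain
   ("Big Mac burger, McDonald's").
4. **Renaming** — display names in common usage, originals retained as
   synonyms, keywords appended.
5. **Portions** — household measures converted via gram weights or
   volume × density, standard sets (e.g. glass sizes for alcoholic
   beverages), and a universal 100 g/mL fallback.
6. **Search** — deterministic tiered ranking: curated keyword shortlists,
   then exact-name matches, then all-tokens whole-word matches
   alphabetically, then substring matches; queries and names are
   normalised identically (hyphens deleted, apostrophes deleted,
   `&` ≡ `and`).
7. **Diary + SUS** — an append-only event log with a 3 a.m. logging-day
   reset that blocks retrospective edits, manual-entry flagging for
   researcher follow-up, and System Usability Scale scoring
   (odd items score − 1, even items 5 − score, total × 2.5).

A seeded synthetic-fixture generator (`generate_fixture()`) emulates the
reference-database structure — nested codes, complete nutrient panels,
planted mergeable clusters, planted removal categories, chain menus with
planted incomplete items — with a ground-truth manifest, so the whole
pipeline is testable without redistributing any licensed data.

## Worked example

```r
library(eatkit)

# the removal-ledger arithmetic, from per-reason counts
led <- ledger_from_counts(
  c(ingredient = 608, captured_by_chain = 81, indigenous = 52,
    supplement = 25, child_food = 16, not_consumed_or_undefined = 912),
  original_size = 5740)
summarize_ledger(led)
#> # A tibble: 6 × 3
#>   reason_code                   n pct_of_removed
#> 1 ingredient                  608          35.9
#> 2 captured_by_chain            81           4.78
#> 3 indigenous                   52           3.07
#> 4 supplement                   25           1.48
#> 5 child_food                   16           0.94
#> 6 not_consumed_or_undefined   912          53.8
#> total removed: 1694 of 5740 (29.51%)

# a full pipeline run on a synthetic fixture with known ground truth
fx  <- generate_fixture(fixture_params(), seed = 42)
out <- curate_database(fx$foods, fx$rules, fx$consumed_ids, tolerance = 0.10)
#  foods in: 120   removed: 21   merge groups: 4   final: 93   conservation: TRUE

summarize_merges(out$groups, nrow(fx$foods))
#> # A tibble: 1 × 4
#>   n_members n_groups n_reduced pct_members_of_original
#> 1        10        4         6                    8.33

idx <- build_search_index(out$merged, fx$keyword_map)
search_foods(idx, "apple", limit = 5)
#> # A tibble: 5 × 4
#>    rank  tier food_id  display_name
#> 1     1     0 11A01001 Apple, golden
#> 2     2     0 11A01002 Apple, wholemeal
#> 3     3     0 11A01003 Apple, red
#> 4     4     0 11A01004 Apple, reduced fat/toasted/frozen
#> 5     5     0 11A01007 Apple, sweetened
```

The ledger table gives each removal reason's count and its share of all
removals (2 dp); the trailing line gives the total against the original
database. `curate_database()` reports the conservation identity
`final = original − removed − Σ(group size − 1)`, here `93 = 120 − 21 − 6`.
In the search result, tier 0 marks a curated keyword shortlist; row 4 shows
a planted cluster merged into one record with its variety descriptors
joined.

A thin CLI over the same functions ships in `inst/cli/eatkit.R`
(`validate`, `sus`, `simulate`, `search` subcommands).

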