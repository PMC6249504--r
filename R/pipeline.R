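#' Run the full curation pipeline
#'
#' Convenience wrapper running the four database-construction steps in
#' order: (1) reason-coded removal against the rule set and consumed-ID
#' list, (2) nutrient-similarity merging within minor categories, (3)
#' integration of branded chain records, and (4) name simplification via
#' the rename map. Renaming is applied before chain integration so merged
#' display names and synonyms are settled when the final database is
#' assembled; chain items arrive already carrying their chain-suffixed
#' names.
#'
#' @param records Generic food database tibble.
#' @param rules List of [removal_rule()]s.
#' @param consumed_ids Character vector of consumed food IDs (or `NULL`).
#' @param tolerance Merge tolerance (relative, default 0.10).
#' @param renames Optional [rename_map()].
#' @param chain_records Optional chain food tibble from
#'   [chain_to_food_records()].
#' @return List with `final` (integrated database), `kept`, `ledger`,
#'   `groups`, `merged`, and `conservation` — the identity
#'   `nrow(merged) == original - removed - sum(size - 1)` evaluated as a
#'   logical.
#' @export
curate_database <- function(records, rules = list(), consumed_ids = NULL,
                            tolerance = 0.10, renames = NULL,
                            chain_records = NULL) {
  removal <- apply_removal_rules(records, rules, consumed_ids)
  groups <- build_merge_groups(removal$kept, tolerance = tolerance)
  merged <- apply_merge_groups(removal$kept, groups, rename_map = renames)
  if (!is.null(renames)) merged <- apply_renames(merged, renames)
  final <- if (!is.null(chain_records) && nrow(chain_records) > 0) {
    integrate_databases(merged, chain_records)
  } else merged
  conservation <- nrow(merged) ==
    nrow(records) - nrow(removal$ledger$entries) - sum(groups$size - 1)
  list(final = final, kept = removal$kept, ledger = removal$ledger,
       groups = groups, merged = merged, conservation = conservation)
}
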