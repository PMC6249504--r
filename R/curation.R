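removal_reasons <- function() {
  c("ingredient", "captured_by_chain", "indigenous", "supplement",
    "child_food", "not_consumed_or_undefined")
}

#' Define a removal rule
#'
#' Curation removes foods a young-adult cohort would not log: raw
#' ingredients, fast foods superseded by branded chain data, foods specific
#' to other populations, supplements, children's foods, and foods with no
#' recorded consumption. A rule pairs a reason code with a matcher — an
#' explicit food-ID list and/or a set of classification codes (any of
#' major/sub-major/minor) — and rules fire in order, first match wins.
#'
#' @param reason_code One of `ingredient`, `captured_by_chain`, `indigenous`,
#'   `supplement`, `child_food`, `not_consumed_or_undefined`.
#' @param food_ids Explicit food IDs matched by the rule.
#' @param class_codes Classification codes (2, 3 or 5 characters) matched
#'   against the food's major/sub-major/minor codes.
#' @return A `removal_rule` list.
#' @export
removal_rule <- function(reason_code, food_ids = character(0), class_codes = character(0)) {
  if (!reason_code %in% removal_reasons()) {
    abort(sprintf("config error: unknown reason_code '%s' (known: %s)",
                  reason_code, paste(removal_reasons(), collapse = ", ")))
  }
  structure(list(reason_code = reason_code,
                 food_ids = as.character(food_ids),
                 class_codes = as.character(class_codes)),
            class = "removal_rule")
}

#' Apply removal rules to a food database
#'
#' Walks the ordered rule list; each food is removed by the first rule that
#' matches it (so a food matching several rules is counted once, under the
#' earliest). Foods matching no rule are then checked against the consumed-ID
#' list: foods absent from it are removed with reason
#' `not_consumed_or_undefined`. Kept rows preserve input order, and
#' `nrow(kept) + nrow(ledger entries)` always equals the original size.
#'
#' @param records Food database tibble.
#' @param rules List of [removal_rule()]s, in priority order.
#' @param consumed_ids Character vector of food IDs with recorded
#'   consumption, or `NULL` to skip the consumption screen.
#' @return List with `kept` (food tibble) and `ledger` (a `removal_ledger`:
#'   entries tibble `food_id`/`reason_code` plus the original size).
#' @export
apply_removal_rules <- function(records, rules, consumed_ids = NULL) {
  reasons <- vapply(rules, function(r) {
    if (!inherits(r, "removal_rule")) abort("rules must be removal_rule objects")
    r$reason_code
  }, character(1))
  if (anyDuplicated(reasons)) abort("config error: reason codes must be unique within a rule set")

  assigned <- rep(NA_character_, nrow(records))
  for (r in rules) {
    hit <- records$food_id %in% r$food_ids |
      records$major_code %in% r$class_codes |
      records$sub_major_code %in% r$class_codes |
      records$minor_code %in% r$class_codes
    assigned[is.na(assigned) & hit] <- r$reason_code
  }
  if (!is.null(consumed_ids)) {
    assigned[is.na(assigned) & !(records$food_id %in% consumed_ids)] <-
      "not_consumed_or_undefined"
  }

  removed <- !is.na(assigned)
  ledger <- new_removal_ledger(
    tibble(food_id = records$food_id[removed], reason_code = assigned[removed]),
    original_size = nrow(records)
  )
  list(kept = records[!removed, ], ledger = ledger)
}

new_removal_ledger <- function(entries, original_size) {
  stopifnot(original_size >= nrow(entries))
  structure(list(entries = entries, original_size = original_size),
            class = "removal_ledger")
}

#' Build a removal ledger from per-reason counts
#'
#' Convenience constructor for ledger arithmetic when only the per-reason
#' tallies are known (e.g. reproducing a published removal breakdown):
#' entries get placeholder IDs.
#'
#' @param counts Named integer vector, reason code -> number removed.
#' @param original_size Number of foods before removal.
#' @return A `removal_ledger`.
#' @export
ledger_from_counts <- function(counts, original_size) {
  entries <- tibble(
    food_id = paste0("n/a:", seq_len(sum(counts))),
    reason_code = rep(names(counts), counts)
  )
  new_removal_ledger(entries, original_size)
}

#' @export
print.removal_ledger <- function(x, ...) {
  cat(sprintf("<removal_ledger> %d of %d foods removed\n",
              nrow(x$entries), x$original_size))
  if (nrow(x$entries)) print(summarize_ledger(x), ...)
  invisible(x)
}

#' Summarise a removal ledger
#'
#' Per-reason counts with each reason's share of all removals, plus the
#' total removed and its share of the original database, percentages
#' half-even rounded to 2 decimal places. An empty ledger yields an all-zero
#' summary rather than a division error.
#'
#' @param ledger A `removal_ledger`.
#' @return A `ledger_summary` tibble (`reason_code`, `n`, `pct_of_removed`)
#'   with attributes `total_removed`, `original_size`, `pct_of_original`.
#' @export
#' @examples
#' led <- ledger_from_counts(c(a = 3, b = 1), original_size = 16)
#' summarize_ledger(led)  # shares 75.00 / 25.00, 25.00% of original
summarize_ledger <- function(ledger) {
  stopifnot(inherits(ledger, "removal_ledger"))
  if (ledger$original_size <= 0) abort("original_size must be positive")
  total <- nrow(ledger$entries)
  if (total == 0) {
    tab <- tibble(reason_code = character(0), n = integer(0), pct_of_removed = numeric(0))
    pct_original <- 0
  } else {
    counts <- table(ledger$entries$reason_code)
    # preserve first-appearance order of reasons in the ledger
    ord <- unique(ledger$entries$reason_code)
    tab <- tibble(
      reason_code = ord,
      n = as.integer(counts[ord]),
      pct_of_removed = round(100 * as.integer(counts[ord]) / total, 2)
    )
    pct_original <- round(100 * total / ledger$original_size, 2)
  }
  structure(tab, class = c("ledger_summary", class(tab)),
            total_removed = total,
            original_size = ledger$original_size,
            pct_of_original = pct_original)
}

#' @export
print.ledger_summary <- function(x, ...) {
  NextMethod()
  cat(sprintf("total removed: %d of %d (%.2f%%)\n",
              attr(x, "total_removed"), attr(x, "original_size"),
              attr(x, "pct_of_original")))
  invisible(x)
}

#' Nutrient-profile similarity predicate
#'
#' Two foods are merge candidates when, for energy and every tracked
#' nutrient, the relative difference is within the tolerance. The predicate
#' is symmetric and division-safe: `|a - b| / max(a, b) <= tolerance`, with
#' two zeros counting as similar and a zero against a positive value as
#' dissimilar (their ratio is 1).
#'
#' @param a,b Named numeric vectors holding `energy` and every nutrient in
#'   `panel`; both foods must be on the same basis and panel-complete.
#' @param tolerance Maximum relative difference, e.g. `0.10` for +/-10%.
#' @param panel Nutrient codes compared in addition to energy.
#' @return `TRUE` if every compared value is within tolerance.
#' @export
#' @examples
#' a <- setNames(rep(1, 26), c("energy", tracked_nutrients()))
#' b <- a; b["energy"] <- 1.09
#' nutrient_similar(a, b, tolerance = 0.10)  # 0.09/1.09 <= 0.10
nutrient_similar <- function(a, b, tolerance = 0.10, panel = tracked_nutrients()) {
  keys <- c("energy", panel)
  miss <- setdiff(keys, names(a)[!is.na(a[keys])])
  miss <- union(miss, setdiff(keys, names(b)[!is.na(b[keys])]))
  if (length(miss)) {
    abort(paste0("usage error: missing tracked nutrient value(s): ",
                 paste(miss, collapse = ", ")))
  }
  av <- as.numeric(a[keys]); bv <- as.numeric(b[keys])
  mx <- pmax(av, bv)
  dev <- ifelse(mx == 0, 0, abs(av - bv) / mx)
  all(dev <= tolerance)
}

# Pairwise max relative deviation matrix for a profile matrix (rows = foods,
# cols = energy + panel). Vectorised core shared by build_merge_groups and
# the reported per-group deviation.
pairwise_max_rel_dev <- function(m) {
  n <- nrow(m)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      mx <- pmax(m[i, ], m[j, ])
      dev <- ifelse(mx == 0, 0, abs(m[i, ] - m[j, ]) / mx)
      out[i, j] <- out[j, i] <- max(dev)
    }
  }
  out
}

#' Group nutritionally similar foods for merging
#'
#' Within each (minor category, basis) stratum, foods are grouped so that
#' every pair inside a group satisfies [nutrient_similar()] at the given
#' tolerance (a clique, not a connected component: pairwise similarity is
#' not transitive, and requiring cliques guarantees the tolerance criterion
#' for every merged pair). Grouping is deterministic: foods are sorted by
#' ID, each group is seeded by the smallest unassigned ID, and the
#' smallest-ID food similar to *all* current members is added repeatedly
#' until none qualifies. Singletons are not emitted.
#'
#' @param records Panel-complete food database tibble.
#' @param tolerance Relative tolerance passed to the similarity predicate.
#' @param panel Nutrient codes compared in addition to energy.
#' @return Tibble of merge groups: `minor_code`, `basis`, `member_ids`
#'   (list-column), `size`, `max_rel_deviation`.
#' @export
build_merge_groups <- function(records, tolerance = 0.10, panel = tracked_nutrients()) {
  cols <- c("energy", panel)
  groups <- list()
  strata <- split(seq_len(nrow(records)),
                  paste(records$minor_code, records$basis, sep = "\r"))
  for (idx in strata[radix_sort(names(strata))]) {
    if (length(idx) < 2) next
    idx <- idx[radix_order(records$food_id[idx])]
    m <- as.matrix(records[idx, cols])
    if (anyNA(m)) {
      abort(sprintf("usage error: records must be panel-complete (minor %s)",
                    records$minor_code[idx[1]]))
    }
    dev <- pairwise_max_rel_dev(m)
    sim <- dev <= tolerance
    assigned <- rep(FALSE, length(idx))
    for (s in seq_along(idx)) {
      if (assigned[s]) next
      members <- s
      assigned[s] <- TRUE
      repeat {
        cand <- which(!assigned & apply(sim[, members, drop = FALSE], 1, all))
        if (!length(cand)) break
        nxt <- cand[1]  # rows already in ID order
        members <- c(members, nxt)
        assigned[nxt] <- TRUE
      }
      if (length(members) >= 2) {
        groups[[length(groups) + 1]] <- tibble(
          minor_code = records$minor_code[idx[members[1]]],
          basis = records$basis[idx[members[1]]],
          member_ids = list(records$food_id[idx[members]]),
          size = length(members),
          max_rel_deviation = max(dev[members, members])
        )
      }
    }
  }
  if (!length(groups)) {
    return(tibble(minor_code = character(0), basis = character(0),
                  member_ids = list(), size = integer(0),
                  max_rel_deviation = numeric(0)))
  }
  bind_rows(groups)
}

#' Merge a group of similar foods into one record
#'
#' Every nutrient of the merged record is the unweighted arithmetic mean of
#' the members' values; the merged food takes the smallest member ID. The
#' display name joins the distinct trailing variety descriptors with `/`
#' when the members share a common name stem (`"Apple, green"` +
#' `"Apple, golden"` -> `"Apple, green/golden"`); otherwise a configured
#' rename-map entry for the smallest-ID member, or failing that its own
#' name, is used. Portions are unioned (first occurrence of each label wins)
#' and every member's original name is retained as a synonym.
#'
#' @param members Food tibble of at least two panel-comparable records from
#'   one (minor category, basis) stratum.
#' @param rename_map Optional [rename_map()] consulted for the merged name.
#' @return A one-row food database tibble.
#' @export
merge_group <- function(members, rename_map = NULL) {
  if (nrow(members) < 2) abort("usage error: a merge group needs >= 2 members")
  if (length(unique(members$minor_code)) != 1 || length(unique(members$basis)) != 1) {
    abort("merge group members must share minor_code and basis")
  }
  ord <- radix_order(members$food_id)
  members <- members[ord, ]
  merged <- members[1, ]

  name <- joined_variety_name(members$display_name)
  if (is.na(name) && !is.null(rename_map)) {
    hit <- rename_lookup(rename_map, members$original_name[1])
    if (!is.null(hit)) name <- hit$display_name
  }
  if (is.na(name)) name <- members$display_name[1]
  merged$display_name <- name

  for (nm in nutrient_columns()) merged[[nm]] <- mean(members[[nm]])
  merged$synonyms <- list(radix_sort(unique(c(
    unlist(members$synonyms), setdiff(members$original_name, name)
  ))))
  merged$keywords <- list(radix_sort(unique(unlist(members$keywords))))
  pool <- bind_rows(members$portions)
  merged$portions <- list(pool[!duplicated(pool$label), ])
  merged
}

# "Apple, green" + "Apple, golden" -> "Apple, green/golden" when all names
# share the stem before the final comma segment; NA when they don't.
joined_variety_name <- function(names) {
  parts <- strsplit(names, ", ", fixed = TRUE)
  if (any(lengths(parts) < 2)) return(NA_character_)
  stems <- vapply(parts, function(p) paste(p[-length(p)], collapse = ", "), character(1))
  if (length(unique(stems)) != 1) return(NA_character_)
  tails <- unique(vapply(parts, function(p) p[length(p)], character(1)))
  paste0(stems[1], ", ", paste(tails, collapse = "/"))
}

#' Apply merge groups to a database
#'
#' Replaces each group's members with the merged record from
#' [merge_group()], leaving ungrouped foods untouched; output keeps input
#' order with the merged record at the position of its smallest-ID member.
#' The conservation identity holds:
#' `nrow(out) == nrow(records) - sum(size - 1)`.
#'
#' @param records Food database tibble.
#' @param groups Output of [build_merge_groups()].
#' @param rename_map Optional [rename_map()] for merged display names.
#' @return Food database tibble after merging.
#' @export
apply_merge_groups <- function(records, groups, rename_map = NULL) {
  if (nrow(groups) == 0) return(records)
  drop <- character(0)
  out <- records
  for (g in seq_len(nrow(groups))) {
    ids <- groups$member_ids[[g]]
    rows <- match(ids, out$food_id)
    merged <- merge_group(out[rows, ], rename_map = rename_map)
    keep_row <- match(merged$food_id, out$food_id)
    out[keep_row, ] <- merged
    drop <- c(drop, setdiff(ids, merged$food_id))
  }
  out[!out$food_id %in% drop, ]
}

#' Summarise merging
#'
#' Reports both readings of "foods combined": the number of member foods
#' that took part in a merge, and the number of groups they collapsed into;
#' the difference is the net reduction in database size.
#'
#' @param groups Output of [build_merge_groups()].
#' @param original_size Database size the percentage is computed against.
#' @return Tibble with `n_members`, `n_groups`, `n_reduced`,
#'   `pct_members_of_original` (2 dp).
#' @export
summarize_merges <- function(groups, original_size) {
  n_members <- sum(groups$size)
  tibble(
    n_members = n_members,
    n_groups = nrow(groups),
    n_reduced = n_members - nrow(groups),
    pct_members_of_original = round(100 * n_members / original_size, 2)
  )
}

#' Build a rename map
#'
#' Long reference-database names are shortened to common usage
#' (`"Soft drink, lemonade, regular"` -> `"Lemonade"`), sometimes carrying
#' several synonyms in one display name
#' (`"Ham & pineapple/Hawaiian pizza"`). Lookup is exact on the original
#' name.
#'
#' @param entries Tibble/data frame with columns `original_name`,
#'   `display_name`, and optionally `synonyms`, `keywords` (either
#'   list-columns or `|`-packed strings).
#' @return A `rename_map`.
#' @export
rename_map <- function(entries) {
  entries <- as_tibble(entries)
  stopifnot(all(c("original_name", "display_name") %in% names(entries)))
  if (any(!nzchar(entries$display_name))) abort("display names must be non-empty")
  for (col in c("synonyms", "keywords")) {
    if (!col %in% names(entries)) entries[[col]] <- list(character(0))[rep(1, nrow(entries))]
    if (is.character(entries[[col]])) entries[[col]] <- unpack_list_col(entries[[col]])
  }
  structure(entries, class = c("rename_map", class(entries)))
}

rename_lookup <- function(map, original_name) {
  i <- match(original_name, map$original_name)
  if (is.na(i)) return(NULL)
  list(display_name = map$display_name[i],
       synonyms = map$synonyms[[i]], keywords = map$keywords[[i]])
}

#' Apply a rename map to a database
#'
#' Records whose original name has a map entry take the mapped display name;
#' the original name is retained as a synonym, and mapped synonyms/keywords
#' are appended (never replacing existing ones). Records without an entry
#' pass through unchanged. Duplicate resulting display names are allowed
#' but reported with a warning, since they make foods indistinguishable in
#' search result lists.
#'
#' @param records Food database tibble.
#' @param map A [rename_map()].
#' @return The renamed food tibble.
#' @export
apply_renames <- function(records, map) {
  idx <- match(records$original_name, map$original_name)
  hit <- which(!is.na(idx))
  for (i in hit) {
    e <- idx[i]
    new_name <- map$display_name[e]
    records$synonyms[[i]] <- unique(c(records$synonyms[[i]],
                                      setdiff(records$original_name[i], new_name),
                                      map$synonyms[[e]]))
    records$keywords[[i]] <- unique(c(records$keywords[[i]], map$keywords[[e]]))
    records$display_name[i] <- new_name
  }
  dup <- unique(records$display_name[duplicated(records$display_name)])
  if (length(dup)) {
    warn(paste0("duplicate display name(s) after rename: ",
                paste(utils::head(dup, 5), collapse = "; ")))
  }
  records
}
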