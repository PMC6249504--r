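test_that("removal follows first-match semantics and the consumed-ID screen", {
  db <- dplyr::bind_rows(lapply(1:10, function(i) {
    make_food(sprintf("16A10%03d", i), sprintf("Food %02d", i))
  }))
  rules <- list(
    removal_rule("ingredient", food_ids = c("16A10001", "16A10002")),
    removal_rule("supplement", food_ids = c("16A10002", "16A10003"))
  )
  consumed <- setdiff(db$food_id, "16A10009")
  res <- apply_removal_rules(db, rules, consumed)
  expect_equal(nrow(res$kept), 6)
  counts <- table(res$ledger$entries$reason_code)
  expect_equal(unname(counts[["ingredient"]]), 2)      # 002 counted here, not supplement
  expect_equal(unname(counts[["supplement"]]), 1)
  expect_equal(unname(counts[["not_consumed_or_undefined"]]), 1)
  # partition identity and kept-order preservation
  expect_equal(nrow(res$kept) + nrow(res$ledger$entries), nrow(db))
  expect_identical(res$kept$food_id, setdiff(db$food_id, res$ledger$entries$food_id))

  # empty rules + everything consumed is the identity
  res0 <- apply_removal_rules(db, list(), db$food_id)
  expect_identical(res0$kept, db)
  expect_equal(nrow(res0$ledger$entries), 0)

  expect_error(removal_rule("bogus_reason"), "unknown reason_code")
})

test_that("removal rules match on classification codes", {
  db <- dplyr::bind_rows(
    make_food("16A10001", "Apple"),
    make_food("16A10002", "Pear"),
    make_food("17B20001", "Formula")
  )
  res <- apply_removal_rules(db, list(removal_rule("child_food", class_codes = "17B")),
                             db$food_id)
  expect_equal(res$ledger$entries$food_id, "17B20001")
})

test_that("ledger summaries reproduce hand-computed shares", {
  s <- summarize_ledger(ledger_from_counts(c(a = 3, b = 1), 16))
  expect_equal(s$pct_of_removed, c(75, 25))
  expect_equal(attr(s, "pct_of_original"), 25)

  s1 <- summarize_ledger(ledger_from_counts(c(x = 1), 2))
  expect_equal(s1$pct_of_removed, 100)
  expect_equal(attr(s1, "pct_of_original"), 50)

  empty <- new_ledger <- apply_removal_rules(make_food("16A10001", "Apple"),
                                             list(), "16A10001")$ledger
  s0 <- summarize_ledger(empty)
  expect_equal(nrow(s0), 0)
  expect_equal(attr(s0, "pct_of_original"), 0)
})

test_that("ledger percentages sum to 100 within rounding slack", {
  for (seed in 1:5) {
    fx <- generate_fixture(fixture_params(), seed = seed)
    res <- apply_removal_rules(fx$foods, fx$rules, fx$consumed_ids)
    s <- summarize_ledger(res$ledger)
    expect_lt(abs(sum(s$pct_of_removed) - 100), 0.021)
  }
})

test_that("the similarity predicate is symmetric, zero-safe and tolerance-exact", {
  a <- full_panel(5)
  expect_true(nutrient_similar(a, a, tolerance = 0))

  b <- full_panel(5, energy = 5.45)           # energy 100 vs 109 scaled: 0.45/5.45
  a2 <- full_panel(5, energy = 5)
  expect_true(nutrient_similar(a2, b, 0.10))  # 9/109 = 0.0826
  expect_true(nutrient_similar(b, a2, 0.10))

  c1 <- full_panel(5, sugars = 0)
  c2 <- full_panel(5, sugars = 0.5)
  expect_false(nutrient_similar(c1, c2, 0.10))  # zero vs positive: ratio 1
  expect_true(nutrient_similar(c1, c1, 0.10))   # both zero: similar

  d <- full_panel(5, energy = 5.6)
  expect_false(nutrient_similar(a2, d, 0.10))   # 0.6/5.6 = 0.107

  expect_error(nutrient_similar(full_panel(NA), a, 0.1), "missing tracked")
})

test_that("merge grouping matches the brute-force clique oracle", {
  for (seed in c(11, 12)) {
    fx <- generate_fixture(fixture_params(n_foods = 60, n_clusters = 3,
                                          cluster_sizes = c(3, 2, 4)), seed = seed)
    got <- build_merge_groups(fx$foods, 0.10)
    expect_setequal(id_sets(got), id_sets(oracle_merge_groups(fx$foods, 0.10)))
  }
})

test_that("pairwise-similar chains are split into cliques, not components", {
  # A~B and B~C but A!~C: only {A, B} merges, C stays out
  mk <- function(id, e) make_food(id, paste("Food", id), full_panel(5, energy = e))
  db <- dplyr::bind_rows(mk("16A10001", 100), mk("16A10002", 108), mk("16A10003", 117))
  g <- build_merge_groups(db, 0.10)
  expect_equal(id_sets(g), list(c("16A10001", "16A10002")))
  expect_setequal(id_sets(g), id_sets(oracle_merge_groups(db, 0.10)))
})

test_that("identical foods in different minor categories never merge", {
  db <- dplyr::bind_rows(make_food("16A10001", "Apple, green"),
                         make_food("16A20001", "Apple, green"))
  expect_equal(nrow(build_merge_groups(db, 0.10)), 0)
})

test_that("foods on different bases never merge", {
  a <- make_food("16A10001", "Juice, apple")
  b <- make_food("16A10002", "Juice, pear", basis = "per_100_mL")
  expect_equal(nrow(build_merge_groups(dplyr::bind_rows(a, b), 0.10)), 0)
})

test_that("merging averages nutrients, keeps the smallest ID and joins variety names", {
  a <- make_food("16A10002", "Apple, green", full_panel(2, energy = 250),
                 portions = tibble::tibble(label = "1 apple", amount = 150))
  b <- make_food("16A10001", "Apple, golden", full_panel(4, energy = 260),
                 portions = tibble::tibble(label = c("1 apple", "1 cup"),
                                           amount = c(150, 120)))
  m <- merge_group(dplyr::bind_rows(a, b))
  expect_equal(m$food_id, "16A10001")
  expect_equal(m$energy, 255)
  expect_equal(m$display_name, "Apple, golden/green")  # members in ID order
  expect_equal(m$protein, 3)                           # mean of 2 and 4
  expect_setequal(m$synonyms[[1]], c("Apple, golden", "Apple, green"))
  expect_setequal(m$portions[[1]]$label, c("1 apple", "1 cup"))
  # every merged nutrient lies within the members' range
  for (nm in c("energy", tracked_nutrients())) {
    expect_gte(m[[nm]], min(a[[nm]], b[[nm]]))
    expect_lte(m[[nm]], max(a[[nm]], b[[nm]]))
  }
  expect_error(merge_group(a), ">= 2 members")
})

test_that("conservation holds through removal and merging on fixtures", {
  for (seed in 1:5) {
    fx <- generate_fixture(fixture_params(), seed = seed)
    out <- curate_database(fx$foods, fx$rules, fx$consumed_ids, tolerance = 0.10)
    expect_true(out$conservation)
    expect_equal(nrow(out$merged),
                 nrow(fx$foods) - nrow(out$ledger$entries) - sum(out$groups$size - 1))
  }
})

test_that("merging is idempotent on well-separated databases", {
  fx <- generate_fixture(fixture_params(), seed = 21)
  g <- build_merge_groups(fx$foods, 0.10)
  merged <- apply_merge_groups(fx$foods, g)
  expect_equal(nrow(build_merge_groups(merged, 0.10)), 0)
})

test_that("renames swap display names, keep originals as synonyms and append keywords", {
  db <- dplyr::bind_rows(
    make_food("13A01001", "Soft drink, lemonade, regular", keywords = "drink"),
    make_food("15A02001", "Pizza, ham & pineapple"),
    make_food("16A10001", "Apple, green")
  )
  map <- rename_map(tibble::tibble(
    original_name = c("Soft drink, lemonade, regular", "Pizza, ham & pineapple"),
    display_name = c("Lemonade", "Ham & pineapple/Hawaiian pizza"),
    synonyms = list(character(0), "Hawaiian pizza"),
    keywords = list("lemonade", "pizza")
  ))
  out <- apply_renames(db, map)
  expect_equal(out$display_name[1], "Lemonade")
  expect_true("Soft drink, lemonade, regular" %in% out$synonyms[[1]])
  expect_setequal(out$keywords[[1]], c("drink", "lemonade"))
  expect_equal(out$display_name[2], "Ham & pineapple/Hawaiian pizza")
  expect_identical(out[3, ], db[3, ])   # unmapped record untouched

  expect_identical(apply_renames(db, rename_map(tibble::tibble(
    original_name = character(0), display_name = character(0)))), db)
})

test_that("duplicate display names after renaming warn but pass through", {
  db <- dplyr::bind_rows(make_food("16A10001", "Apple, red"),
                         make_food("16A10002", "Apple, crimson"))
  map <- rename_map(tibble::tibble(
    original_name = c("Apple, red", "Apple, crimson"),
    display_name = c("Apple", "Apple")))
  expect_warning(out <- apply_renames(db, map), "duplicate display name")
  expect_equal(out$display_name, c("Apple", "Apple"))
})
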