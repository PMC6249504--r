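# Shared fixture builders for the test suite. Everything is constructed in
# code; nothing is read from disk except files the tests write themselves.

# A full named nutrient vector (energy + the 25-nutrient panel), all values
# `fill` unless overridden by name.
full_panel <- function(fill = 1, ...) {
  p <- setNames(rep(fill, 26), c("energy", tracked_nutrients()))
  over <- c(...)
  p[names(over)] <- over
  p
}

# One panel-complete generic food with minimal ceremony.
make_food <- function(food_id, display_name, panel = full_panel(), ...) {
  food_record(food_id, display_name, nutrients = panel, ...)
}

# Brute-force merge-grouping oracle, independent of build_merge_groups: it
# enumerates all pairs with the symmetric max-denominator deviation computed
# from first principles, builds the similarity graph per (minor, basis)
# stratum, and extracts smallest-ID-seeded cliques greedily.
oracle_merge_groups <- function(records, tolerance) {
  cols <- c("energy", tracked_nutrients())
  out <- list()
  key <- paste(records$minor_code, records$basis)
  for (k in sort(unique(key))) {
    rows <- which(key == k)
    ids <- records$food_id[rows]
    rows <- rows[order(ids)]
    ids <- sort(ids)
    n <- length(rows)
    if (n < 2) next
    adj <- matrix(FALSE, n, n)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j) next
        a <- as.numeric(records[rows[i], cols])
        b <- as.numeric(records[rows[j], cols])
        ok <- TRUE
        for (t in seq_along(a)) {
          m <- max(a[t], b[t])
          if (m > 0 && abs(a[t] - b[t]) / m > tolerance) { ok <- FALSE; break }
        }
        adj[i, j] <- ok
      }
    }
    left <- seq_len(n)
    while (length(left)) {
      seed <- left[1]
      clique <- seed
      left <- left[-1]
      repeat {
        cand <- left[vapply(left, function(x) all(adj[x, clique]), logical(1))]
        if (!length(cand)) break
        clique <- c(clique, cand[1])
        left <- setdiff(left, cand[1])
      }
      if (length(clique) >= 2) out[[length(out) + 1]] <- ids[sort(clique)]
    }
  }
  out
}

id_sets <- function(groups) {
  if (is.data.frame(groups)) groups <- groups$member_ids
  unname(lapply(groups, sort))
}

# Database encoding the foods from the usability study's problem queries,
# with the final design's synonym/keyword annotations in place.
usability_db <- function() {
  f <- function(id, name, syn = character(0), kw = character(0)) {
    make_food(id, name, synonyms = syn, keywords = kw)
  }
  dplyr::bind_rows(
    f("11A01001", "Skim cow's milk"),
    f("11A01002", "Full cream cow's milk"),
    f("11A02001", "Milk chocolate"),
    f("11A02002", "Milkshake, chocolate"),
    f("11A03001", "Coconut milk"),
    f("12A01001", "Ice cream, vanilla"),
    f("12A01002", "Ice cream, chocolate"),
    f("13A01001", "Coca-Cola", syn = "Coke"),
    f("13A01002", "Lemonade", syn = "Soft drink, lemonade, regular"),
    f("13A02001", "Orange juice"),
    f("13A02002", "Orange fruit drink 25% juice"),
    f("13A02003", "Apple juice"),
    f("14A01001", "Sanitarium Weet-Bix Original"),
    f("15A01001", "Deep fried hot potato chips, from restaurant/takeout",
      syn = c("hot chips", "fries")),
    f("15A02001", "Ham & pineapple/Hawaiian pizza"),
    f("16A01001", "Raw banana", kw = "banana"),
    f("16A01002", "Banana smoothie"),
    f("17A01001", "Raw sugar", kw = "sugar"),
    f("18A01001", "Leg ham"),
    f("18A01002", "Processed ham and chicken luncheon meat"),
    f("19A01001", "Fried chicken egg in butter")
  )
}

usability_keywords <- function() {
  list(
    milk = c("11A01001", "11A01002", "11A03001"),
    ham = c("18A01001", "18A01002")
  )
}

# (query, expected food) regression pairs drawn from the usability-study
# failure cases, expected to succeed under the final design.
usability_regressions <- function() {
  tibble::tribble(
    ~query,              ~expected_id,
    "weetbix",           "14A01001",
    "weet-bix",          "14A01001",
    "cows milk",         "11A01001",
    "cow's milk",        "11A01001",
    "coke",              "13A01001",
    "coca-cola",         "13A01001",
    "icecream",          "12A01001",
    "ice cream",         "12A01001",
    "hot chips",         "15A01001",
    "ham & pineapple",   "15A02001",
    "ham and pineapple", "15A02001",
    "orange juice",      "13A02001",
    "milk",              "11A01001",
    "sugar",             "17A01001",
    "banana",            "16A01001"
  )
}
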