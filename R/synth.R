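#' @importFrom stats rnorm runif
NULL

# Largest-remainder apportionment: split `total` across `weights` so the
# integer parts sum exactly to `total` and shares track the weights.
apportion <- function(total, weights) {
  if (total == 0 || sum(weights) == 0) return(setNames(rep(0L, length(weights)), names(weights)))
  q <- total * weights / sum(weights)
  fl <- floor(q)
  rem <- total - sum(fl)
  if (rem > 0) {
    top <- radix_order(-(q - fl), seq_along(q))[seq_len(rem)]
    fl[top] <- fl[top] + 1
  }
  setNames(as.integer(fl), names(weights))
}

# Typical per-100 g magnitudes used as lognormal medians per nutrient; the
# fixtures are structural stand-ins, not realistic Australian foods.
nutrient_scales <- function() {
  c(energy = 800, protein = 8, total_fat = 10, saturated_fat = 4,
    monounsaturated_fat = 4, polyunsaturated_fat = 2, carbohydrate = 20,
    sugars = 8, starch = 10, dietary_fibre = 3, sodium = 300,
    potassium = 250, calcium = 80, iron = 1.5, magnesium = 25, zinc = 1,
    phosphorus = 120, thiamin = 0.1, riboflavin = 0.15, niacin = 2,
    folate = 30, vitamin_a = 50, vitamin_c = 10, vitamin_e = 1,
    cholesterol = 20, moisture = 60)
}

#' Default fixture-generation parameters
#'
#' The knobs of the synthetic AUSNUT-like world: database size and hierarchy
#' shape, planted merge clusters (within-cluster spread and the
#' between-profile separation ladder), removal-category proportions, chain
#' menus with planted incomplete items, and the diary/SUS stream sizes.
#' Cluster spread is the maximum pairwise relative deviation inside a
#' planted cluster (default 0.8 x tolerance, safely inside the merge
#' criterion), and the separation ladder guarantees non-cluster profiles
#' differ by well over 2.5 x tolerance in every nutrient.
#'
#' @param ... Named overrides of the defaults.
#' @return Parameter list.
#' @export
fixture_params <- function(...) {
  p <- list(
    n_foods = 120,
    n_minor_categories = 16,
    n_clusters = 4,
    cluster_sizes = c(3, 2, 3, 2),
    tolerance = 0.10,
    cluster_spread = NULL,           # default 0.8 * tolerance
    removal_props = c(ingredient = 0.06, captured_by_chain = 0.01,
                      indigenous = 0.008, supplement = 0.005,
                      child_food = 0.003, not_consumed_or_undefined = 0.09),
    n_chains = 3,
    items_per_chain = 12,
    incomplete_fraction = 0.25,
    per_serve_fraction = 0.5,
    measures_fraction = 0.6,
    n_participants = 5,
    diary_days = 3,
    events_per_day = 6,
    manual_fraction = 0.1,
    n_sus_responses = 15,
    defect_counts = NULL             # e.g. c(negative_nutrient = 2, ...)
  )
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad)) abort(paste0("unknown fixture parameter(s): ", paste(bad, collapse = ", ")))
  p[names(over)] <- over
  if (is.null(p$cluster_spread)) p$cluster_spread <- 0.8 * p$tolerance
  if (length(p$cluster_sizes) != p$n_clusters) {
    p$cluster_sizes <- rep_len(p$cluster_sizes, p$n_clusters)
  }
  p
}

#' Generation profile mirroring the published database breakdown
#'
#' Returns fixture parameters whose removal-category proportions follow the
#' published removal ledger (608 : 81 : 52 : 25 : 16 : 912 out of 5740) and
#' whose generic/chain split follows the published 4046 : 2229 composition,
#' scaled to `n` generic foods. At `n = 5740` the expected removal counts
#' equal the printed ledger exactly; at smaller scales counts are
#' largest-remainder apportioned.
#'
#' @param n Number of generic foods to generate.
#' @return Parameter list (see [fixture_params()]) with an
#'   `expected_removals` attribute giving the apportioned per-reason counts.
#' @export
paper_scale_profile <- function(n = 574) {
  printed <- c(ingredient = 608, captured_by_chain = 81, indigenous = 52,
               supplement = 25, child_food = 16,
               not_consumed_or_undefined = 912)
  original <- 5740
  removed_total <- round(n * sum(printed) / original)
  counts <- apportion(removed_total, printed)
  n_chain <- round(n * 2229 / original)
  n_chains <- max(1L, min(3L, n_chain))
  p <- fixture_params(
    n_foods = n,
    n_minor_categories = max(1L, round(n / 8)),
    n_clusters = if (n >= 40) 4L else 0L,
    removal_props = counts / max(n, 1),
    n_chains = n_chains,
    items_per_chain = if (n_chain > 0) ceiling(n_chain / n_chains) else 0L,
    incomplete_fraction = 0
  )
  attr(p, "expected_removals") <- counts
  p
}

fixture_nouns <- function() {
  c("Apple", "Pear", "Banana", "Orange", "Bread", "Roll", "Milk", "Yoghurt",
    "Cheese", "Beef", "Chicken", "Lamb", "Rice", "Pasta", "Potato", "Carrot",
    "Pea", "Bean", "Lettuce", "Tomato", "Biscuit", "Cake", "Juice", "Cordial",
    "Cereal", "Porridge", "Soup", "Stew", "Pie", "Sausage", "Fish", "Prawn",
    "Nut", "Seed", "Butter", "Spread", "Sauce", "Dressing", "Tea", "Coffee")
}

fixture_adjectives <- function() {
  c("green", "golden", "red", "plain", "toasted", "boiled", "baked", "fried",
    "grilled", "frozen", "canned", "dried", "fresh", "smoked", "raw",
    "regular", "reduced fat", "wholemeal", "white", "sweetened")
}

with_fixture_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  force(code)
}

#' Generate a synthetic fixture world
#'
#' Builds an AUSNUT-like generic food table (8-character IDs with nested
#' 2/3/5-character classification codes, complete 26-value nutrient panels),
#' planted merge clusters, a reason-coded removal assignment with a matching
#' consumed-ID list and rule set, chain menus with planted incomplete items,
#' a household-measures table, rename and keyword maps, diary event streams,
#' SUS responses, and a ground-truth manifest describing all of it. The same
#' seed and parameters always regenerate identical content (and, via
#' [write_fixture()], byte-identical files).
#'
#' Profile construction guarantees the merge structure: within a minor
#' category, distinct profile slots sit on a multiplicative ladder (factor
#' 1.6 per slot, +/-1% jitter), so any two foods from different slots differ
#' by >30% in every nutrient, while planted cluster members share one slot
#' with per-nutrient factors inside `[1 - s/2, 1 + s/2]`
#' (`s = cluster_spread`), bounding their pairwise relative deviation by
#' `s / (1 + s/2)` — inside the merge tolerance by construction.
#'
#' @param params [fixture_params()] list.
#' @param seed Integer RNG seed.
#' @return A `fixture` list: `foods`, `clusters`, `removal` (tibble
#'   food_id/reason_code), `rules`, `consumed_ids`, `chain_menus` (list of
#'   tibbles), `incomplete_chain`, `measures`, `rename_map`, `keyword_map`,
#'   `diary`, `sus` (matrix), `defects`, and `manifest`.
#' @export
generate_fixture <- function(params = fixture_params(), seed = 1L) {
  p <- params
  with_fixture_seed(seed, {
    total_cluster_members <- sum(p$cluster_sizes)
    extra <- total_cluster_members - p$n_clusters      # members beyond their slot
    if (p$n_foods > 0 && p$n_foods < total_cluster_members) {
      abort("config error: n_foods smaller than the planted cluster membership")
    }
    n_slots <- p$n_foods - extra
    n_minor <- min(p$n_minor_categories, max(n_slots, 1))
    if (p$n_clusters > n_minor && p$n_foods > 0) {
      abort("config error: more clusters than minor categories")
    }

    # -- hierarchy ---------------------------------------------------------
    minors <- tibble(
      idx = seq_len(n_minor),
      major_code = sprintf("%02d", 11 + (seq_len(n_minor) - 1) %/% 8),
      sub_major_code = paste0(sprintf("%02d", 11 + (seq_len(n_minor) - 1) %/% 8),
                              LETTERS[1 + ((seq_len(n_minor) - 1) %% 8) %/% 2]),
      minor_code = paste0(sprintf("%02d", 11 + (seq_len(n_minor) - 1) %/% 8),
                          LETTERS[1 + ((seq_len(n_minor) - 1) %% 8) %/% 2],
                          sprintf("%02d", 1 + (seq_len(n_minor) - 1) %% 2)),
      noun = rep_len(fixture_nouns(), n_minor)
    )

    foods <- empty_food_db()
    clusters <- list()
    if (p$n_foods > 0) {
      slots_per_minor <- apportion(n_slots, rep(1, n_minor))
      if (any(slots_per_minor == 0) && p$n_clusters > sum(slots_per_minor > 0)) {
        abort("config error: clusters larger than the category layout allows")
      }
      cluster_minors <- which(slots_per_minor >= 1)[seq_len(p$n_clusters)]
      scales <- nutrient_scales()
      adjs <- fixture_adjectives()
      rows <- list()
      for (mi in seq_len(n_minor)) {
        k <- slots_per_minor[mi]
        if (k == 0) next
        base <- scales * exp(rnorm(length(scales), 0, 0.3))
        if (mi %% 5 == 0) base["dietary_fibre"] <- 0  # exercise the zero rule
        cl_pos <- match(mi, cluster_minors)
        cl_slot <- if (!is.na(cl_pos)) sample.int(k, 1) else NA
        serial <- 0
        minor_adjs <- sample(adjs)
        for (slot in seq_len(k)) {
          slot_profile <- base * 1.6^(slot - 1)
          n_here <- if (!is.na(cl_slot) && slot == cl_slot) p$cluster_sizes[cl_pos] else 1
          member_ids <- character(0)
          for (m in seq_len(n_here)) {
            serial <- serial + 1
            jit <- if (n_here > 1) {
              runif(length(scales), 1 - p$cluster_spread / 2, 1 + p$cluster_spread / 2)
            } else {
              runif(length(scales), 0.99, 1.01)
            }
            prof <- round(slot_profile * jit, 4)
            id <- paste0(minors$minor_code[mi], sprintf("%03d", serial))
            adj <- minor_adjs[(serial - 1) %% length(minor_adjs) + 1]
            rows[[length(rows) + 1]] <- food_record(
              food_id = id,
              display_name = paste0(minors$noun[mi], ", ", adj),
              nutrients = setNames(prof, names(scales)),
              major_label = paste(minors$noun[mi], "products and dishes"),
              sub_major_label = paste(minors$noun[mi], "group"),
              minor_label = tolower(minors$noun[mi])
            )
            member_ids <- c(member_ids, id)
          }
          if (n_here > 1) clusters[[length(clusters) + 1]] <- member_ids
        }
      }
      foods <- bind_rows(rows)
    }

    # -- planted removals --------------------------------------------------
    cluster_ids <- unlist(clusters)
    eligible <- setdiff(foods$food_id, cluster_ids)
    counts <- apportion(round(p$n_foods * sum(p$removal_props)),
                        p$removal_props)
    if (sum(counts) > length(eligible)) {
      abort("config error: removal proportions exceed the non-cluster food pool")
    }
    picked <- if (sum(counts) > 0) sample(eligible, sum(counts)) else character(0)
    removal <- tibble(
      food_id = picked,
      reason_code = rep(names(counts), counts)
    )
    removal <- removal[radix_order(removal$food_id), ]
    explicit <- setdiff(removal_reasons(), "not_consumed_or_undefined")
    rules <- lapply(explicit, function(rc) {
      removal_rule(rc, food_ids = removal$food_id[removal$reason_code == rc])
    })
    consumed_ids <- setdiff(foods$food_id,
                            removal$food_id[removal$reason_code == "not_consumed_or_undefined"])

    # -- chain menus -------------------------------------------------------
    chain_names <- c("Burger Barn", "Pizza Plaza", "Creamy Cones")[seq_len(p$n_chains)]
    chain_cats <- c("burger", "pizza", "ice_cream")[seq_len(p$n_chains)]
    lab_scales <- nutrient_scales()[c("energy", label_nutrients())]
    chain_menus <- list()
    incomplete_chain <- tibble(chain_name = character(0), item_name = character(0),
                               missing = character(0))
    for (ci in seq_along(chain_names)) {
      nit <- p$items_per_chain
      if (nit == 0) next
      menu <- tibble(
        item_name = paste0(sample(c("Mega", "Classic", "Double", "Spicy", "Mini",
                                    "Golden", "Crispy", "Deluxe", "Garden", "Smoky",
                                    "Sweet", "Zesty"), nit, replace = nit > 12), " ",
                           rep_len(c("Burger", "Wrap", "Box", "Stack", "Roll", "Cup"), nit),
                           " ", sprintf("%02d", seq_len(nit))),
        basis = ifelse(runif(nit) < p$per_serve_fraction, "per_serve", "per_100"),
        serve_size = round(runif(nit, 150, 450)),
        unit = ifelse(ci == p$n_chains & p$n_chains > 2, "mL", "g"),
        category = chain_cats[ci],
        available = TRUE
      )
      vals <- vapply(names(lab_scales), function(nm) {
        round(lab_scales[[nm]] * exp(rnorm(nit, 0, 0.4)), 2)
      }, numeric(nit))
      if (nit == 1) vals <- matrix(vals, nrow = 1, dimnames = list(NULL, names(lab_scales)))
      per_serve <- menu$basis == "per_serve"
      vals[per_serve, ] <- round(vals[per_serve, , drop = FALSE] * menu$serve_size[per_serve] / 100, 2)
      for (nm in colnames(vals)) menu[[nm]] <- vals[, nm]
      n_bad <- round(p$incomplete_fraction * nit)
      if (n_bad > 0) {
        bad_rows <- sample.int(nit, n_bad)
        for (r in bad_rows) {
          drop_nm <- sample(c("energy", label_nutrients()), 1)
          menu[[drop_nm]][r] <- NA_real_
          incomplete_chain <- bind_rows(incomplete_chain, tibble(
            chain_name = chain_names[ci], item_name = menu$item_name[r],
            missing = drop_nm))
        }
      }
      chain_menus[[chain_names[ci]]] <- menu
    }

    # -- measures ----------------------------------------------------------
    n_meas <- round(p$measures_fraction * nrow(foods))
    measures <- if (n_meas > 0) {
      ids <- sample(foods$food_id, n_meas)
      labels <- sample(c("1 cup", "1 tablespoon", "1 slice", "1 piece", "1 glass"),
                       n_meas, replace = TRUE)
      vol <- labels == "1 glass"
      tibble(
        food_id = ids,
        measure_label = labels,
        grams_per_measure = ifelse(vol, NA_real_, round(runif(n_meas, 10, 300))),
        volume_per_measure = ifelse(vol, 200, NA_real_),
        density = ifelse(vol, round(runif(n_meas, 0.9, 1.1), 2), NA_real_)
      )[radix_order(ids), ]
    } else {
      tibble(food_id = character(0), measure_label = character(0),
             grams_per_measure = numeric(0), volume_per_measure = numeric(0),
             density = numeric(0))
    }

    # -- rename + keyword maps --------------------------------------------
    # maps reference foods that survive the whole pipeline: merging keeps
    # only the smallest ID of each planted cluster
    cluster_nonsurvivors <- unlist(lapply(clusters, function(ids) setdiff(ids, min(ids))))
    kept_pool <- setdiff(foods$food_id, c(removal$food_id, cluster_nonsurvivors))
    ren_ids <- utils::head(radix_sort(kept_pool), min(5, length(kept_pool)))
    renames <- rename_map(tibble(
      original_name = foods$display_name[match(ren_ids, foods$food_id)],
      display_name = paste("Common",
                           tolower(foods$display_name[match(ren_ids, foods$food_id)])),
      synonyms = lapply(seq_along(ren_ids), function(i) sprintf("alt name %d", i)),
      keywords = lapply(seq_along(ren_ids), function(i) character(0))
    ))
    kw_minors <- unique(foods$minor_code[match(kept_pool, foods$food_id)])
    kw_minors <- utils::head(radix_sort(kw_minors), 4)
    keyword_map <- lapply(kw_minors, function(mc) {
      radix_sort(intersect(foods$food_id[foods$minor_code == mc], kept_pool))
    })
    names(keyword_map) <- tolower(minors$noun[match(kw_minors, minors$minor_code)])
    keyword_map <- keyword_map[lengths(keyword_map) > 0]

    # -- diary + SUS -------------------------------------------------------
    diary <- diary_store()
    if (p$n_participants > 0 && nrow(foods) > 0) {
      t0 <- as.POSIXct("2018-03-05 07:00:00", tz = "UTC")
      for (pid in sprintf("P%02d", seq_len(p$n_participants))) {
        for (d in seq_len(p$diary_days)) {
          for (ev in seq_len(p$events_per_day)) {
            ts <- t0 + (d - 1) * 86400 + (ev - 1) * 7200 + round(runif(1, 0, 3600))
            manual <- runif(1) < p$manual_fraction
            entry <- diary_entry(
              participant_id = pid, timestamp = ts,
              food_ref = if (manual) paste("mystery dish", ev) else sample(foods$food_id, 1),
              amount = sample(1:3, 1), unit = "100 g",
              location = sample(location_taxonomy(), 1),
              is_manual = manual,
              meal_slot = c("breakfast", "snack", "lunch", "snack", "dinner", "snack")[(ev - 1) %% 6 + 1]
            )
            diary <- add_entry(diary, entry, now = ts)
          }
        }
      }
    }
    sus <- if (p$n_sus_responses > 0) {
      m <- matrix(0L, p$n_sus_responses, 10)
      for (i in seq_len(p$n_sus_responses)) {
        m[i, c(1, 3, 5, 7, 9)] <- sample(2:5, 5, replace = TRUE, prob = c(1, 2, 4, 3))
        m[i, c(2, 4, 6, 8, 10)] <- sample(1:4, 5, replace = TRUE, prob = c(3, 4, 2, 1))
      }
      m
    } else matrix(0L, 0, 10)

    # -- planted defects ---------------------------------------------------
    defects <- tibble(code = character(0), food_id = character(0))
    if (!is.null(p$defect_counts) && nrow(foods) > 1) {
      pool <- radix_sort(setdiff(foods$food_id, c(cluster_ids, removal$food_id)))
      take <- function(n) {
        ids <- utils::head(pool, n); pool <<- setdiff(pool, ids); ids
      }
      dc <- p$defect_counts
      if (!is.na(dc["negative_nutrient"] %||% NA)) {
        ids <- take(dc[["negative_nutrient"]])
        foods$sodium[match(ids, foods$food_id)] <- -1
        defects <- bind_rows(defects, tibble(code = "negative_nutrient", food_id = ids))
      }
      if (!is.na(dc["panel_incomplete"] %||% NA)) {
        ids <- take(dc[["panel_incomplete"]])
        foods$zinc[match(ids, foods$food_id)] <- NA_real_
        defects <- bind_rows(defects, tibble(code = "panel_incomplete", food_id = ids))
      }
      if (!is.na(dc["nonpositive_portion"] %||% NA)) {
        ids <- take(dc[["nonpositive_portion"]])
        for (id in ids) {
          foods$portions[[match(id, foods$food_id)]] <-
            tibble(label = "bad portion", amount = 0)
        }
        defects <- bind_rows(defects, tibble(code = "nonpositive_portion", food_id = ids))
      }
      if (!is.na(dc["duplicate_id"] %||% NA) && dc[["duplicate_id"]] > 0) {
        ids <- take(dc[["duplicate_id"]])
        foods <- bind_rows(foods, foods[match(ids, foods$food_id), ])
        defects <- bind_rows(defects, tibble(code = "duplicate_id", food_id = ids))
      }
    }

    manifest <- structure(list(
      seed = seed,
      params = p,
      n_foods = nrow(foods),
      clusters = clusters,
      removal = removal,
      removal_counts = counts,
      incomplete_chain = incomplete_chain,
      defects = defects,
      n_chain_items = sum(vapply(chain_menus, nrow, integer(1)))
    ), class = "fixture_manifest")

    list(foods = foods, clusters = clusters, removal = removal, rules = rules,
         consumed_ids = consumed_ids, chain_menus = chain_menus,
         incomplete_chain = incomplete_chain, measures = measures,
         rename_map = renames, keyword_map = keyword_map, diary = diary,
         sus = sus, defects = defects, manifest = manifest)
  })
}

#' @export
print.fixture_manifest <- function(x, ...) {
  cat(sprintf("<fixture_manifest> seed %d: %d foods, %d planted cluster(s), %d planted removal(s), %d chain item(s) (%d incomplete), %d planted defect(s)\n",
              x$seed, x$n_foods, length(x$clusters), nrow(x$removal),
              x$n_chain_items, nrow(x$incomplete_chain), nrow(x$defects)))
  invisible(x)
}

#' Write a fixture world to disk
#'
#' Serialises every component of a [generate_fixture()] result as plain
#' text: the food table and measures as CSV, consumed IDs as one-per-line
#' text, chain menus as per-chain CSVs, the rename map as CSV, the keyword
#' map as YAML, diary events as JSON lines, SUS responses as CSV, and the
#' manifest as JSON. Regenerating with the same seed and parameters and
#' re-writing yields byte-identical files.
#'
#' @param fx Fixture list from [generate_fixture()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fx, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "chains"), showWarnings = FALSE)
  write_database(fx$foods, file.path(dir, "foods.csv"))
  readr::write_csv(fx$measures, file.path(dir, "measures.csv"), na = "", eol = "\n",
                   progress = FALSE)
  writeLines(radix_sort(fx$consumed_ids), file.path(dir, "consumed_ids.txt"))
  for (ch in names(fx$chain_menus)) {
    slug <- gsub("[^a-z0-9]+", "-", tolower(ch))
    readr::write_csv(fx$chain_menus[[ch]], file.path(dir, "chains", paste0(slug, ".csv")),
                     na = "", eol = "\n", progress = FALSE)
  }
  ren <- as_tibble(fx$rename_map)
  ren$synonyms <- pack_list_col(ren$synonyms)
  ren$keywords <- pack_list_col(ren$keywords)
  readr::write_csv(ren, file.path(dir, "renames.csv"), na = "", eol = "\n",
                   progress = FALSE)
  writeLines(yaml::as.yaml(fx$keyword_map), file.path(dir, "keywords.yaml"))
  write_diary_log(fx$diary, file.path(dir, "diary.jsonl"))
  sus <- as.data.frame(fx$sus)
  names(sus) <- paste0("item", 1:10)
  readr::write_csv(sus, file.path(dir, "sus.csv"), eol = "\n", progress = FALSE)
  manifest <- fx$manifest
  manifest$removal <- as.data.frame(manifest$removal)
  manifest$incomplete_chain <- as.data.frame(manifest$incomplete_chain)
  manifest$defects <- as.data.frame(manifest$defects)
  json <- jsonlite::toJSON(unclass(manifest), auto_unbox = TRUE, digits = NA,
                           null = "null", pretty = TRUE)
  writeLines(json, file.path(dir, "manifest.json"))
  invisible(dir)
}
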