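#' Convert a household measure to grams or millilitres
#'
#' A measure entry carries either the weight of one measure directly, or a
#' volume plus a density from which the weight is derived
#' (`volume x density`). When both paths are present and disagree by more
#' than 0.5% the gram weight wins and the discrepancy is reported as a
#' warning. The conversion is linear in the quantity.
#'
#' @param entry One measure-entry row (see [read_measures()]).
#' @param quantity Positive number of measures consumed.
#' @return Amount in the food's unit (grams or millilitres).
#' @export
#' @examples
#' e <- tibble::tibble(food_id = "x", measure_label = "1 glass",
#'                     grams_per_measure = NA, volume_per_measure = 200,
#'                     density = 1.04)
#' grams_from_measure(e, 1)  # 208
grams_from_measure <- function(entry, quantity) {
  if (!is.numeric(quantity) || length(quantity) != 1 || is.na(quantity) || quantity <= 0) {
    abort("usage error: quantity must be a single positive number")
  }
  g <- entry$grams_per_measure
  v <- entry$volume_per_measure
  d <- entry$density
  have_g <- !is.na(g)
  have_vd <- !is.na(v) && !is.na(d)
  if (!have_g && !have_vd) {
    abort("usage error: measure entry has neither a gram weight nor volume+density")
  }
  if (have_g && have_vd) {
    derived <- v * d
    if (abs(derived - g) / max(derived, g) > 0.005) {
      warn(sprintf("measure '%s' (%s): gram weight %.6g disagrees with volume x density %.6g; using the gram weight",
                   entry$measure_label, entry$food_id, g, derived))
    }
  }
  per_measure <- if (have_g) g else v * d
  quantity * per_measure
}

#' Default standard portion sets
#'
#' Beyond the household measures recorded for each food, some food
#' categories get standard portion options regardless of the measures file —
#' the canonical example being standard glass sizes for alcoholic
#' beverages. Each set names the classification codes it applies to
#' (matched against major/sub-major/minor) and the portions it adds. Sizes
#' here follow common Australian serving ware; they are configuration, not
#' data.
#'
#' @param alcohol_codes Classification codes identifying alcoholic
#'   beverages in the database at hand.
#' @return List of standard-set definitions.
#' @export
standard_portion_sets <- function(alcohol_codes = c("29")) {
  list(
    list(
      name = "alcoholic_glasses",
      class_codes = alcohol_codes,
      portions = tibble(
        label = c("1 small glass (285 mL)", "1 large glass (425 mL)",
                  "1 pint (570 mL)"),
        amount = c(285, 425, 570)
      )
    )
  )
}

#' Attach portion options to a food
#'
#' Builds the food's portion list from its household measures (each measure
#' becomes one option via [grams_from_measure()]), adds any standard-set
#' portions whose classification rule matches, deduplicates by label
#' (first occurrence wins), and always appends the universal fallback
#' option `"100 g"` / `"100 mL"` so every food can be entered by weight or
#' volume. Re-applying the function changes nothing (idempotent).
#'
#' @param food One-row food database tibble.
#' @param measures Measure-entry tibble (any foods; filtered to this food).
#' @param standard_sets Standard-set list from [standard_portion_sets()].
#' @return The food with its `portions` list-column populated.
#' @export
assign_portions <- function(food, measures = NULL,
                            standard_sets = standard_portion_sets()) {
  stopifnot(nrow(food) == 1)
  opts <- list(food$portions[[1]])
  if (!is.null(measures)) {
    mine <- measures[measures$food_id == food$food_id, , drop = FALSE]
    if (nrow(mine)) {
      opts[[length(opts) + 1]] <- tibble(
        label = mine$measure_label,
        amount = vapply(seq_len(nrow(mine)),
                        function(i) grams_from_measure(mine[i, ], 1), numeric(1))
      )
    }
  }
  codes <- c(food$major_code, food$sub_major_code, food$minor_code)
  for (set in standard_sets) {
    if (any(codes %in% set$class_codes)) opts[[length(opts) + 1]] <- set$portions
  }
  opts[[length(opts) + 1]] <- tibble(label = paste0("100 ", food$unit), amount = 100)
  pool <- bind_rows(opts)
  if (any(!is.finite(pool$amount) | pool$amount <= 0)) {
    abort(sprintf("non-positive portion amount for food %s", food$food_id))
  }
  food$portions <- list(pool[!duplicated(pool$label), ])
  food
}

#' Attach portions to every food in a database
#'
#' Vectorised wrapper over [assign_portions()].
#'
#' @inheritParams assign_portions
#' @param records Food database tibble.
#' @return The database with portions populated.
#' @export
assign_all_portions <- function(records, measures = NULL,
                                standard_sets = standard_portion_sets()) {
  rows <- lapply(seq_len(nrow(records)), function(i) {
    assign_portions(records[i, ], measures, standard_sets)
  })
  bind_rows(rows)
}
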