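#' Tracked nutrient panel
#'
#' The curated database tracks energy plus 25 nutrients per 100 g (or
#' 100 mL) for every generic food. The panel membership is a configuration
#' artifact: similarity merging, completeness validation and the synthetic
#' generator all read this list, so swapping it re-targets the whole
#' pipeline. The default covers the macronutrients, fatty-acid classes,
#' sugars and starch, fibre, the headline minerals and vitamins, cholesterol
#' and moisture.
#'
#' @return Character vector of 25 nutrient codes (energy excluded; energy is
#'   always tracked and carried in its own `energy` column, in kJ).
#' @export
#' @examples
#' length(tracked_nutrients())  # 25
tracked_nutrients <- function() {
  c(
    "protein", "total_fat", "saturated_fat", "monounsaturated_fat",
    "polyunsaturated_fat", "carbohydrate", "sugars", "starch",
    "dietary_fibre", "sodium", "potassium", "calcium", "iron",
    "magnesium", "zinc", "phosphorus", "thiamin", "riboflavin",
    "niacin", "folate", "vitamin_a", "vitamin_c", "vitamin_e",
    "cholesterol", "moisture"
  )
}

#' Mandatory label nutrients for chain foods
#'
#' Branded ready-to-eat chain items carry only the nutrients mandatory on an
#' Australian Nutrition Information Panel: energy plus these six. A chain
#' record is "label-complete" when energy and all six are present.
#'
#' @return Character vector of the six label nutrient codes (energy excluded).
#' @export
label_nutrients <- function() {
  c("protein", "total_fat", "saturated_fat", "carbohydrate", "sugars", "sodium")
}

# All nutrient columns a food table carries, energy first.
nutrient_columns <- function() c("energy", tracked_nutrients())
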