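#' Nutrient keys tracked by the pipeline
#'
#' Eight nutrients are carried through every stage: total energy intake,
#' the three macronutrients, sugar, fiber, and the two micronutrients
#' (cholesterol, sodium). Units are fixed per nutrient: kcal for energy,
#' grams for carbohydrate/fat/protein/fiber/sugar, milligrams for
#' cholesterol and sodium. All per-item amounts are per consumed portion;
#' aggregated intakes are per day.
#'
#' @return Character vector of the eight nutrient names, in canonical order.
#' @export
#' @examples
#' nutrient_keys()
#' nutrient_unit("sodium")
nutrient_keys <- function() {
  c("energy", "carbohydrate", "fat", "protein",
    "fiber", "sugar", "cholesterol", "sodium")
}

.nutrient_units <- c(
  energy = "kcal", carbohydrate = "g", fat = "g", protein = "g",
  fiber = "g", sugar = "g", cholesterol = "mg", sodium = "mg"
)

#' @rdname nutrient_keys
#' @param nutrient One of `nutrient_keys()`.
#' @export
nutrient_unit <- function(nutrient) {
  nutrient <- match_nutrient(nutrient)
  unname(.nutrient_units[nutrient])
}

match_nutrient <- function(nutrient) {
  match.arg(nutrient, nutrient_keys(), several.ok = TRUE)
}

ref_col <- function(nutrient) paste0("ref_", nutrient)
app_col <- function(nutrient) paste0("app_", nutrient)
ref_cols <- function() ref_col(nutrient_keys())
app_cols <- function() app_col(nutrient_keys())

diary_columns <- function() {
  c("participant_id", "phase", "day", "item_label", "portion_g",
    ref_cols(), app_cols())
}
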