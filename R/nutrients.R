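#' Nutrient registry
#'
#' The canonical set of 16 nutrients tracked per food: energy, the two
#' macronutrients, and 13 vitamins and minerals.  Food composition is stored
#' per 100 g edible portion; individual specifications are per day.
#'
#' @return A data frame with one row per nutrient and columns:
#' \describe{
#'   \item{key}{canonical nutrient name used throughout the package}
#'   \item{unit}{unit of the amount (per 100 g edible for foods, per day for
#'     specifications)}
#'   \item{class}{`"energy"`, `"macro"` or `"micro"`}
#'   \item{food_column}{column name in a food table}
#'   \item{has_upper_limit}{whether a toxicity upper limit is enforced
#'     (vitamin A, vitamin C, niacin, calcium, iron)}
#'   \item{percentile_adjustable}{whether the daily specification may be moved
#'     between the 1st and 99th percentile.  Vitamin A is a recommended safe
#'     intake and is never adjusted; no adjustment factors are published for
#'     pantothenic acid or magnesium.}
#' }
#' @export
nutrient_registry <- function() {
  key <- c("energy", "protein", "fat",
           "vitamin_a", "vitamin_c", "vitamin_b1", "vitamin_b2", "niacin",
           "vitamin_b6", "folic_acid", "vitamin_b12", "pantothenic_acid",
           "calcium", "iron", "magnesium", "zinc")
  unit <- c("kcal", "g", "g",
            "ug_re", "mg", "mg", "mg", "mg",
            "mg", "ug", "ug", "mg",
            "mg", "mg", "mg", "mg")
  cls <- c("energy", "macro", "macro", rep("micro", 13))
  data.frame(
    key = key,
    unit = unit,
    class = cls,
    food_column = paste0(key, "_", unit),
    has_upper_limit = key %in% c("vitamin_a", "vitamin_c", "niacin",
                                 "calcium", "iron"),
    percentile_adjustable = cls == "micro" &
      !key %in% c("vitamin_a", "pantothenic_acid", "magnesium"),
    stringsAsFactors = FALSE
  )
}

#' @noRd
micro_keys <- function() {
  reg <- nutrient_registry()
  reg$key[reg$class == "micro"]
}

#' @noRd
upper_limit_keys <- function() {
  reg <- nutrient_registry()
  reg$key[reg$has_upper_limit]
}

#' @noRd
food_nutrient_columns <- function() nutrient_registry()$food_column

#' Food groups recognised by the default configuration
#'
#' Fifteen group names covering the archetypes used in assessments.  Groups
#' marked as exceptions are exempt from portion-size scaling: their portions
#' are fixed per group rather than scaled from the reference child.
#'
#' @return Data frame with columns `group` and `scaling_exempt`.
#' @export
food_groups <- function() {
  grp <- c("staples", "legumes", "vegetables", "fruits", "animal products",
           "fish", "oils and fats", "milk and dairy", "eggs",
           "breast milk", "milk powder", "supplements", "infant foods",
           "sugars and confectionery", "condiments")
  data.frame(
    group = grp,
    scaling_exempt = grp %in% c("breast milk", "milk powder", "supplements",
                                "infant foods", "sugars and confectionery",
                                "condiments"),
    stringsAsFactors = FALSE
  )
}
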