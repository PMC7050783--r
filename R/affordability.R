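# Affordability of diets against wealth-group income and essential non-food
# expenditure (typically from a Household Economy Approach).

#' Validate a wealth-group table
#'
#' @param wealth_groups Data frame with columns `name`, `annual_income`,
#'   `annual_nonfood_expenditure`.
#' @return The table, invisibly, if valid.
#' @export
validate_wealth_groups <- function(wealth_groups) {
  required <- c("name", "annual_income", "annual_nonfood_expenditure")
  missing <- setdiff(required, names(wealth_groups))
  if (length(missing) > 0L)
    stop("wealth-group table is missing columns: ",
         paste(missing, collapse = ", "))
  if (any(wealth_groups$annual_income < 0) ||
      any(wealth_groups$annual_nonfood_expenditure < 0))
    stop("income and non-food expenditure must be non-negative")
  invisible(wealth_groups)
}

#' Diet cost as a percentage of wealth-group income
#'
#' Affordability is not calculated for the macronutrients diet.
#'
#' @param annual_diet_cost Annual diet cost, same currency as income.
#' @param wealth_group One row of a validated wealth-group table.
#' @param level Diet level the cost belongs to.
#' @param cumulative If `TRUE`, stack essential non-food expenditure on top
#'   of the diet cost before dividing (the cumulative view used in
#'   affordability charts).
#' @return Percentage of annual income.
#' @export
affordability_pct <- function(annual_diet_cost, wealth_group, level,
                              cumulative = FALSE) {
  if (level == "macronutrients")
    stop("affordability is not calculated for the macronutrients diet")
  income <- wealth_group[["annual_income"]]
  if (is.null(income) || is.na(income) || income == 0)
    stop("undefined affordability: wealth group has no income")
  spend <- annual_diet_cost +
    if (cumulative) wealth_group[["annual_nonfood_expenditure"]] else 0
  100 * spend / income
}

#' Income gap after diet cost and non-food expenditure
#'
#' The money needed to close the gap between income and the cost of the diet
#' plus essential non-food expenditure; clamped at zero (a surplus is not a
#' negative gap).
#'
#' @inheritParams affordability_pct
#' @return Currency per year, `>= 0`.
#' @export
income_gap <- function(wealth_group, annual_diet_cost) {
  max(0, annual_diet_cost + wealth_group[["annual_nonfood_expenditure"]] -
        wealth_group[["annual_income"]])
}

#' Affordability table for an assessment
#'
#' Annual household diet costs expressed against each wealth group: share of
#' income, cumulative share including non-food expenditure, and the income
#' gap.  The macronutrients diet is skipped.
#'
#' @param assessment A `diet_assessment`.
#' @param wealth_groups Validated wealth-group table (defaults to the
#'   scenario's).
#' @return Data frame with one row per household x level x wealth group.
#' @export
affordability_table <- function(assessment,
                                wealth_groups =
                                  assessment$scenario$wealth_groups) {
  validate_wealth_groups(wealth_groups)
  annual <- assessment$annual
  annual <- annual[annual$level != "macronutrients", , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(annual))) {
    for (j in seq_len(nrow(wealth_groups))) {
      wg <- wealth_groups[j, ]
      rows[[length(rows) + 1L]] <- data.frame(
        household = annual$household[i],
        level = annual$level[i],
        wealth_group = wg$name,
        annual_cost = annual$annual_cost[i],
        pct_income = affordability_pct(annual$annual_cost[i], wg,
                                       annual$level[i]),
        pct_income_cumulative = affordability_pct(annual$annual_cost[i], wg,
                                                  annual$level[i],
                                                  cumulative = TRUE),
        income_gap = income_gap(wg, annual$annual_cost[i]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' @rdname validate_wealth_groups
#' @param path File path of `wealth_groups.csv`.
#' @export
read_wealth_groups <- function(path) {
  wg <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_wealth_groups(wg)
  wg
}
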