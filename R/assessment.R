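# Orchestration: one LP per household member x season x diet level, household
# aggregation, seasonal and annual costs, and named override models layered
# on the standard diets.

#' Annual cost from weekly costs per season
#'
#' @param weekly_costs Named numeric vector: weekly cost per season.
#' @param calendar Validated season calendar (names must cover the cost
#'   vector).
#' @return Cost per year: `sum(weekly_cost_s * days_s / 7)`.
#' @export
annual_cost <- function(weekly_costs, calendar) {
  validate_calendar(calendar)
  missing <- setdiff(calendar$name, names(weekly_costs))
  if (length(missing) > 0L)
    stop("no weekly cost for season(s): ", paste(missing, collapse = ", "))
  sum(weekly_costs[calendar$name] * calendar$days / 7)
}

#' Aggregate member solutions into a household view
#'
#' Per-food edible grams are summed across members; purchased (raw) grams are
#' edible grams divided by the edible portion factor; food and group counts
#' are set unions; costs are summed.  All solutions must be for the same
#' season and level.
#'
#' @param solutions List of `diet_solution` objects (one per member) with
#'   amounts.
#' @param foods Validated food table.
#' @return List with `weekly_cost`, `edible_g` (per food), `purchased_g`,
#'   `n_foods`, `n_groups`, `members`.
#' @export
aggregate_household <- function(solutions, foods) {
  if (length(solutions) == 0L) stop("a household must have members")
  levels <- unique(vapply(solutions, `[[`, character(1), "level"))
  if (length(levels) != 1L)
    stop("cannot aggregate solutions across diet levels")
  seasons <- unique(vapply(solutions,
                           function(s) attr(s, "season") %||% "", character(1)))
  if (length(seasons) != 1L)
    stop("cannot aggregate solutions across seasons")
  if (any(vapply(solutions, function(s) is.null(s$weekly_grams), logical(1))))
    stop("all member solutions must have amounts")
  ids <- sort(unique(unlist(lapply(solutions,
                                   function(s) names(s$weekly_grams)))))
  edible <- stats::setNames(numeric(length(ids)), ids)
  for (s in solutions) edible[names(s$weekly_grams)] <-
    edible[names(s$weekly_grams)] + s$weekly_grams
  ep <- foods$edible_portion_factor[match(ids, foods$food_id)]
  eaten <- edible > 1e-6
  groups <- foods$food_group[match(ids[eaten], foods$food_id)]
  list(weekly_cost = sum(vapply(solutions, `[[`, numeric(1), "weekly_cost")),
       edible_g = edible,
       purchased_g = edible / ep,
       n_foods = sum(eaten),
       n_groups = length(unique(groups)),
       members = vapply(solutions, `[[`, character(1), "individual"))
}

#' Apply parameter overrides to a scenario
#'
#' Returns a modified copy; the input scenario is never mutated, so standard
#' diets computed from it remain the untouched baseline.
#'
#' @param scenario A `diet_scenario`.
#' @param price Optional data frame `food_id`, `season_id` (`NA` = all
#'   seasons), `cost_per_100g_edible` setting the seasonal cost directly
#'   (0 models free or subsidised food).
#' @param habits Optional replacement habit table.
#' @return A new `diet_scenario` with an `overrides` attribute.
#' @export
apply_overrides <- function(scenario, price = NULL, habits = NULL) {
  out <- scenario
  if (!is.null(price)) {
    unknown <- setdiff(price$food_id, scenario$foods$food_id)
    if (length(unknown) > 0L)
      stop("price override for unknown food(s): ",
           paste(unknown, collapse = ", "))
    out$price_overrides <- rbind(scenario$price_overrides, price)
  }
  if (!is.null(habits)) out$habits <- habits
  attr(out, "overrides") <- TRUE
  out
}

#' @noRd
apply_price_overrides <- function(seasonal, overrides) {
  if (is.null(overrides)) return(seasonal)
  for (i in seq_len(nrow(overrides))) {
    sel <- seasonal$food_id == overrides$food_id[i]
    if (!is.na(overrides$season_id[i]))
      sel <- sel & seasonal$season_id == overrides$season_id[i]
    seasonal$cost_per_100g_edible[sel] <- overrides$cost_per_100g_edible[i]
  }
  seasonal
}

#' Run a full assessment
#'
#' Solves one weekly LP per household member x season x requested diet level
#' and assembles per-cell solutions, household sums and seasonal/annual
#' costs.  Infeasible cells are re-solved with the shortfall relaxation and
#' flagged, never dropped.
#'
#' @param scenario A `diet_scenario` (from [generate_scenario()],
#'   [read_scenario()] or assembled by hand).
#' @param households Named list of character vectors of individual labels;
#'   default is a single household of all non-infant individuals.
#' @param levels Diet levels to compute (default all four).
#' @param config A [diet_config()].
#' @param name Model name (`"default"` for the standard diets).
#' @return A `diet_assessment`.
#' @export
run_assessment <- function(scenario, households = NULL,
                           levels = diet_levels(), config = diet_config(),
                           name = "default") {
  validate_foods(scenario$foods)
  validate_individuals(scenario$individuals, config$iron_basis)
  validate_calendar(scenario$seasons)
  levels <- match.arg(levels, diet_levels(), several.ok = TRUE)
  if (is.null(households)) {
    labels <- scenario$individuals$label[scenario$individuals$age_months > 12]
    households <- list(household = labels)
  }
  unknown <- setdiff(unlist(households), scenario$individuals$label)
  if (length(unknown) > 0L)
    stop("household member(s) not in individuals table: ",
         paste(unknown, collapse = ", "))

  seasonal <- seasonal_prices(scenario$prices, scenario$foods)
  seasonal <- apply_price_overrides(seasonal, scenario$price_overrides)

  solutions <- list()
  cost_rows <- list()
  tidy_rows <- list()
  for (hh in names(households)) {
    for (season in scenario$seasons$name) {
      ps <- seasonal[seasonal$season_id == season, , drop = FALSE]
      for (level in levels) {
        for (label in households[[hh]]) {
          ind <- scenario$individuals[scenario$individuals$label == label, ,
                                      drop = FALSE]
          problem <- diet_problem(scenario$foods, ps, ind, level,
                                  habits = scenario$habits, config = config)
          sol <- solve_diet(problem)
          if (sol$status == "infeasible") sol <- relaxed_solve(problem)
          attr(sol, "season") <- season
          solutions[[hh]][[season]][[level]][[label]] <- sol
          cost_rows[[length(cost_rows) + 1L]] <- data.frame(
            household = hh, individual = label, season = season,
            level = level, weekly_cost = sol$weekly_cost,
            status = sol$status, stringsAsFactors = FALSE)
          if (!is.null(sol$weekly_grams)) {
            g <- sol$weekly_grams[sol$weekly_grams > 1e-6]
            if (length(g) > 0L)
              tidy_rows[[length(tidy_rows) + 1L]] <- data.frame(
                household = hh, individual = label, season = season,
                level = level, food_id = names(g), weekly_g = unname(g),
                stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  costs <- do.call(rbind, cost_rows)
  tidy <- if (length(tidy_rows) > 0L) do.call(rbind, tidy_rows) else
    data.frame(household = character(0), individual = character(0),
               season = character(0), level = character(0),
               food_id = character(0), weekly_g = numeric(0))

  hh_costs <- stats::aggregate(weekly_cost ~ household + season + level,
                               data = costs, FUN = sum)
  hh_costs$all_optimal <- stats::aggregate(
    status ~ household + season + level, data = costs,
    FUN = function(s) all(s == "optimal"))$status

  annual_rows <- list()
  for (hh in unique(hh_costs$household)) {
    for (level in levels) {
      sel <- hh_costs$household == hh & hh_costs$level == level
      w <- stats::setNames(hh_costs$weekly_cost[sel], hh_costs$season[sel])
      annual_rows[[length(annual_rows) + 1L]] <- data.frame(
        household = hh, level = level,
        annual_cost = annual_cost(w, scenario$seasons),
        all_optimal = all(hh_costs$all_optimal[sel]),
        stringsAsFactors = FALSE)
    }
  }
  structure(list(
    name = name, scenario = scenario, config = config,
    households = households, levels = levels,
    seasonal_prices = seasonal,
    solutions = solutions, costs = costs, tidy = tidy,
    household_costs = hh_costs,
    annual = do.call(rbind, annual_rows)
  ), class = "diet_assessment")
}

#' Run a named override model on top of an assessment
#'
#' The standard diets must exist first; the override scenario is layered
#' functionally, leaving the baseline untouched.
#'
#' @param assessment The default `diet_assessment`.
#' @param name Model name.
#' @param price,habits Overrides as in [apply_overrides()].
#' @param config Optional replacement [diet_config()].
#' @return A new `diet_assessment` for the model run.
#' @export
run_model <- function(assessment, name, price = NULL, habits = NULL,
                      config = NULL) {
  if (!inherits(assessment, "diet_assessment"))
    stop("standard diets must be computed first")
  scenario <- apply_overrides(assessment$scenario, price = price,
                              habits = habits)
  run_assessment(scenario, households = assessment$households,
                 levels = assessment$levels,
                 config = config %||% assessment$config, name = name)
}

#' @export
print.diet_assessment <- function(x, ...) {
  cat("Diet assessment '", x$name, "': ", length(x$households),
      " household(s), ", nrow(x$scenario$seasons), " season(s), levels: ",
      paste(x$levels, collapse = ", "), "\n", sep = "")
  print(x$annual, row.names = FALSE)
  n_relax <- sum(x$costs$status != "optimal")
  if (n_relax > 0)
    cat(n_relax, "cell(s) infeasible (relaxed solutions reported)\n")
  invisible(x)
}

#' @export
summary.diet_assessment <- function(object, ...) {
  print(object)
  cat("\nHousehold weekly cost by season and level:\n")
  print(object$household_costs, row.names = FALSE)
  invisible(object)
}
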