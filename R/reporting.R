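# Report surface: the standard summary-table metrics by day, week, season
# and year, at individual and household scope, with an availability matrix
# declaring which metric exists at which period.  Rounding happens only at
# this boundary (0.1 g, 0.01 currency, 0.1 %); internal values keep full
# precision.

#' Report availability matrix
#'
#' Which summary metric is reported at which period and scope.  Cells mirror
#' the tool's standard summary table, including its quirks: servings, total
#' (raw) weight and nutrient quantities are not annualised, relative shares
#' and affordability only exist from the season upward, the weekly
#' food-group cost exists only for the food-habits nutritious diet, and
#' affordability is never reported for the macronutrients diet.
#'
#' @return Data frame with columns `metric`, `day`, `week`, `season`,
#'   `year`, `individual`, `household`, `restriction`.
#' @export
report_availability <- function() {
  m <- function(metric, day, week, season, year, restriction = "") {
    data.frame(metric = metric, day = day, week = week, season = season,
               year = year, individual = TRUE, household = TRUE,
               restriction = restriction, stringsAsFactors = FALSE)
  }
  rbind(
    m("diet_cost", TRUE, TRUE, TRUE, TRUE),
    m("food_cost", TRUE, TRUE, TRUE, TRUE),
    m("food_cost_share_pct", FALSE, FALSE, TRUE, TRUE),
    m("food_group_weekly_cost", FALSE, TRUE, TRUE, TRUE,
      "food_habits only"),
    m("n_foods", TRUE, TRUE, TRUE, TRUE),
    m("food_servings", TRUE, TRUE, TRUE, FALSE),
    m("n_food_groups", TRUE, TRUE, TRUE, TRUE),
    m("food_edible_weight_g", TRUE, TRUE, TRUE, TRUE),
    m("food_total_weight_g", TRUE, TRUE, TRUE, FALSE),
    m("food_pct_of_edible_weight", FALSE, FALSE, TRUE, TRUE),
    m("nutrient_quantity", TRUE, TRUE, TRUE, FALSE),
    m("food_nutrient_pct_of_spec", TRUE, TRUE, TRUE, TRUE),
    m("achievement_pct", TRUE, TRUE, TRUE, TRUE),
    m("affordability_pct_income", FALSE, FALSE, TRUE, TRUE,
      "not macronutrients")
  )
}

#' @noRd
period_factor <- function(period, season_days) {
  switch(period, day = 1 / 7, week = 1, season = season_days / 7,
         stop("unknown period"))
}

#' @noRd
round_value <- function(value, units) {
  digits <- switch(units, g = 1, currency = 2, pct = 1, count = 0, 3)
  round(value, digits)
}

#' @noRd
report_row <- function(scope, scope_id, season, period, level, metric, item,
                       value, units) {
  data.frame(scope = scope, scope_id = scope_id,
             season = season %||% NA_character_, period = period,
             level = level, metric = metric,
             item = item %||% NA_character_,
             value = round_value(value, units), units = units,
             stringsAsFactors = FALSE)
}

#' @noRd
scope_metric_rows <- function(scope, scope_id, season, level, days,
                              grams, cost_per_g, foods, specs_weekly,
                              provided_weekly, ach, servings_weekly,
                              available) {
  rows <- list()
  add <- function(...) rows[[length(rows) + 1L]] <<- report_row(...)
  avail <- function(metric, period) {
    r <- available[available$metric == metric, ]
    isTRUE(r[[period]])
  }
  idx <- match(names(grams), foods$food_id)
  groups <- foods$food_group[idx]
  ep <- foods$edible_portion_factor[idx]
  food_cost_week <- grams * cost_per_g
  eaten <- grams > 1e-6
  reg <- nutrient_registry()

  for (period in c("day", "week", "season")) {
    f <- period_factor(period, days)
    season_id <- season
    if (avail("diet_cost", period))
      add(scope, scope_id, season_id, period, level, "diet_cost", NULL,
          sum(food_cost_week) * f, "currency")
    if (avail("food_cost", period))
      for (k in which(eaten))
        add(scope, scope_id, season_id, period, level, "food_cost",
            names(grams)[k], food_cost_week[k] * f, "currency")
    if (avail("food_cost_share_pct", period) && sum(food_cost_week) > 0)
      for (k in which(eaten))
        add(scope, scope_id, season_id, period, level,
            "food_cost_share_pct", names(grams)[k],
            100 * food_cost_week[k] / sum(food_cost_week), "pct")
    if (avail("food_group_weekly_cost", period) && level == "food_habits")
      for (g in unique(groups[eaten]))
        add(scope, scope_id, season_id, period, level,
            "food_group_weekly_cost", g,
            sum(food_cost_week[eaten & groups == g]), "currency")
    if (avail("n_foods", period))
      add(scope, scope_id, season_id, period, level, "n_foods", NULL,
          sum(eaten), "count")
    if (avail("n_food_groups", period))
      add(scope, scope_id, season_id, period, level, "n_food_groups", NULL,
          length(unique(groups[eaten])), "count")
    if (avail("food_servings", period) && !is.null(servings_weekly))
      for (k in which(eaten))
        add(scope, scope_id, season_id, period, level, "food_servings",
            names(grams)[k], servings_weekly[k] * f, "servings")
    if (avail("food_edible_weight_g", period))
      for (k in which(eaten))
        add(scope, scope_id, season_id, period, level,
            "food_edible_weight_g", names(grams)[k], grams[k] * f, "g")
    if (avail("food_total_weight_g", period))
      for (k in which(eaten))
        add(scope, scope_id, season_id, period, level,
            "food_total_weight_g", names(grams)[k],
            grams[k] / ep[k] * f, "g")
    if (avail("food_pct_of_edible_weight", period) && sum(grams) > 0)
      for (k in which(eaten))
        add(scope, scope_id, season_id, period, level,
            "food_pct_of_edible_weight", names(grams)[k],
            100 * grams[k] / sum(grams), "pct")
    if (avail("nutrient_quantity", period) && !is.null(provided_weekly))
      for (nm in names(provided_weekly))
        add(scope, scope_id, season_id, period, level, "nutrient_quantity",
            nm, provided_weekly[nm] * f,
            reg$unit[match(nm, reg$key)] %||% "g")
    if (avail("achievement_pct", period) && !is.null(ach))
      for (nm in names(ach))
        if (!is.na(ach[nm]))
          add(scope, scope_id, season_id, period, level, "achievement_pct",
              nm, ach[nm], "pct")
    if (avail("food_nutrient_pct_of_spec", period) &&
        !is.null(specs_weekly)) {
      nut_per_g <- t(as.matrix(foods[idx, reg$food_column])) / 100
      rownames(nut_per_g) <- reg$key
      for (nm in names(specs_weekly)) {
        if (is.na(specs_weekly[nm]) || specs_weekly[nm] <= 0) next
        contrib <- nut_per_g[nm, ] * grams
        for (k in which(eaten & contrib > 1e-9))
          add(scope, scope_id, season_id, period, level,
              "food_nutrient_pct_of_spec",
              paste(names(grams)[k], nm, sep = ":"),
              100 * contrib[k] / specs_weekly[nm], "pct")
      }
    }
  }
  do.call(rbind, rows)
}

#' Render assessment reports to CSV
#'
#' Writes three files: `summary.csv` (every available metric of the report
#' matrix, long format), `solutions.csv` (weekly grams and cost per
#' household, individual, season, level and food) and `warnings.csv`
#' (infeasible cells, nutrients at their upper limits, and the upper-limit
#' warning, machine-readable).
#'
#' @param assessment A `diet_assessment`.
#' @param dir Output directory (created if needed).
#' @param wealth_groups Optional wealth-group table for affordability rows.
#' @return Character vector of the files written, invisibly.
#' @export
render_reports <- function(assessment, dir,
                           wealth_groups =
                             assessment$scenario$wealth_groups) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  available <- report_availability()
  foods <- assessment$scenario$foods
  calendar <- assessment$scenario$seasons
  seasonal <- assessment$seasonal_prices
  reg <- nutrient_registry()

  all_rows <- list()
  warn_rows <- list()
  for (hh in names(assessment$households)) {
    for (season in calendar$name) {
      days <- calendar$days[calendar$name == season]
      ps <- seasonal[seasonal$season_id == season, , drop = FALSE]
      cost_per_g_all <- stats::setNames(ps$cost_per_100g_edible / 100,
                                        ps$food_id)
      for (level in assessment$levels) {
        sols <- assessment$solutions[[hh]][[season]][[level]]
        # individual scope
        for (label in names(sols)) {
          sol <- sols[[label]]
          if (sol$status == "infeasible") {
            warn_rows[[length(warn_rows) + 1L]] <- data.frame(
              household = hh, individual = label, season = season,
              level = level, code = "infeasible",
              detail = paste(sol$warnings, collapse = "; "),
              stringsAsFactors = FALSE)
            next
          }
          grams <- sol$weekly_grams
          specs_weekly <- c(
            energy = sol$provided_weekly[["energy"]] /
              sol$achievement_pct[["energy"]] * 100,
            stats::setNames(rep(NA_real_, 0), character(0)))
          specs_weekly <- vapply(names(sol$achievement_pct), function(nm)
            if (is.na(sol$achievement_pct[[nm]]) ||
                sol$achievement_pct[[nm]] == 0) NA_real_
            else sol$provided_weekly[[nm]] /
              sol$achievement_pct[[nm]] * 100, numeric(1))
          servings <- grams / vapply(
            foods$food_group[match(names(grams), foods$food_id)],
            function(g) portion_size(
              assessment$scenario$individuals[
                assessment$scenario$individuals$label == label, ],
              g, assessment$config$scheme), numeric(1))
          all_rows[[length(all_rows) + 1L]] <- scope_metric_rows(
            "individual", label, season, level, days, grams,
            cost_per_g_all[names(grams)], foods, specs_weekly,
            sol$provided_weekly, sol$achievement_pct, servings, available)
          for (b in sol$binding_upper_limits)
            warn_rows[[length(warn_rows) + 1L]] <- data.frame(
              household = hh, individual = label, season = season,
              level = level, code = "upper_limit_binding", detail = b,
              stringsAsFactors = FALSE)
          for (w in sol$warnings)
            warn_rows[[length(warn_rows) + 1L]] <- data.frame(
              household = hh, individual = label, season = season,
              level = level, code = "upper_limit_reached", detail = w,
              stringsAsFactors = FALSE)
        }
        # household scope
        with_amounts <- Filter(function(s) !is.null(s$weekly_grams), sols)
        if (length(with_amounts) > 0L) {
          agg <- aggregate_household(with_amounts, foods)
          provided <- Reduce(`+`, lapply(with_amounts, `[[`,
                                         "provided_weekly"))
          all_rows[[length(all_rows) + 1L]] <- scope_metric_rows(
            "household", hh, season, level, days, agg$edible_g,
            cost_per_g_all[names(agg$edible_g)], foods, NULL, provided,
            NULL, NULL, available)
        }
      }
    }
  }

  # annual rows and affordability
  annual <- assessment$annual
  for (i in seq_len(nrow(annual)))
    all_rows[[length(all_rows) + 1L]] <- report_row(
      "household", annual$household[i], NULL, "year", annual$level[i],
      "diet_cost", NULL, annual$annual_cost[i], "currency")
  if (!is.null(wealth_groups)) {
    aff <- affordability_table(assessment, wealth_groups)
    for (i in seq_len(nrow(aff)))
      all_rows[[length(all_rows) + 1L]] <- report_row(
        "household", aff$household[i], NULL, "year", aff$level[i],
        "affordability_pct_income", aff$wealth_group[i],
        aff$pct_income[i], "pct")
  }

  summary_df <- do.call(rbind, all_rows)
  warnings_df <- if (length(warn_rows) > 0L) do.call(rbind, warn_rows) else
    data.frame(household = character(0), individual = character(0),
               season = character(0), level = character(0),
               code = character(0), detail = character(0))

  sols_df <- assessment$tidy
  if (nrow(sols_df) > 0L) {
    cpg <- assessment$seasonal_prices
    key <- paste(sols_df$food_id, sols_df$season)
    cost <- cpg$cost_per_100g_edible[
      match(key, paste(cpg$food_id, cpg$season_id))] / 100
    sols_df$weekly_cost <- round(sols_df$weekly_g * cost, 2)
    sols_df$weekly_g <- round(sols_df$weekly_g, 1)
  }

  files <- file.path(dir, c("summary.csv", "solutions.csv", "warnings.csv"))
  utils::write.csv(summary_df, files[1], row.names = FALSE)
  utils::write.csv(sols_df, files[2], row.names = FALSE)
  utils::write.csv(warnings_df, files[3], row.names = FALSE)
  invisible(files)
}
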