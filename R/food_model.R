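# Food composition, market price records and seasonal cost aggregation.
#
# Composition is stored per 100 g edible portion; the LP works internally in
# currency per gram edible so the x100 factor only ever appears at the I/O
# boundary.

#' Validate a food composition table
#'
#' Checks the full food-table contract: all 16 nutrient columns present and
#' non-negative, edible portion factor in (0, 1], food group drawn from the
#' configured group set, iron absorption factor in (0, 1].
#'
#' @param foods Data frame with columns `food_id`, `name`, `food_group`, the
#'   16 nutrient columns of [nutrient_registry()] (amounts per 100 g edible
#'   portion), `edible_portion_factor`, `specific_gravity` (g/ml, `NA` for
#'   non-liquid foods) and `iron_absorption_factor`.
#' @param groups Character vector of allowed food-group names.
#' @return The validated table, invisibly classed as `food_table`.
#' @export
validate_foods <- function(foods, groups = food_groups()$group) {
  required <- c("food_id", "name", "food_group", food_nutrient_columns(),
                "edible_portion_factor", "iron_absorption_factor")
  missing <- setdiff(required, names(foods))
  if (length(missing) > 0L)
    stop("food table is missing columns: ", paste(missing, collapse = ", "))
  if (!"specific_gravity" %in% names(foods)) foods$specific_gravity <- NA_real_
  if (anyDuplicated(foods$food_id))
    stop("duplicate food_id values in food table")
  for (col in food_nutrient_columns()) {
    v <- foods[[col]]
    if (any(is.na(v)) || any(v < 0))
      stop("nutrient column '", col, "' has missing or negative values")
  }
  ep <- foods$edible_portion_factor
  if (any(is.na(ep)) || any(ep <= 0) || any(ep > 1))
    stop("edible_portion_factor must lie in (0, 1]")
  iaf <- foods$iron_absorption_factor
  if (any(is.na(iaf)) || any(iaf <= 0) || any(iaf > 1))
    stop("iron_absorption_factor must lie in (0, 1]")
  bad <- setdiff(unique(foods$food_group), groups)
  if (length(bad) > 0L)
    stop("unknown food group(s): ", paste(bad, collapse = ", "))
  class(foods) <- unique(c("food_table", class(foods)))
  invisible(foods)
}

#' Register a user-supplied food
#'
#' A custom food is accepted only if its edible portion factor and all 16
#' nutrient concentrations per 100 g edible portion are present and
#' non-negative; the rejection message names every missing or invalid field.
#'
#' @param foods Existing validated food table.
#' @param candidate One-row data frame (or coercible list) in the food-table
#'   schema.
#' @return The food table with the candidate appended.
#' @export
add_custom_food <- function(foods, candidate) {
  candidate <- as.data.frame(candidate, stringsAsFactors = FALSE)
  if (nrow(candidate) != 1L) stop("candidate must describe exactly one food")
  problems <- character(0)
  for (i in seq_len(nrow(nutrient_registry()))) {
    reg <- nutrient_registry()[i, ]
    v <- candidate[[reg$food_column]]
    if (is.null(v) || is.na(v) || v < 0)
      problems <- c(problems, gsub("_", " ", reg$key))
  }
  ep <- candidate[["edible_portion_factor"]]
  if (is.null(ep) || is.na(ep) || ep <= 0 || ep > 1)
    problems <- c(problems, "edible portion factor")
  if (length(problems) > 0L)
    stop("food rejected; missing or invalid: ",
         paste(problems, collapse = ", "))
  if (is.null(candidate[["iron_absorption_factor"]]) ||
      is.na(candidate[["iron_absorption_factor"]]))
    candidate$iron_absorption_factor <- 1
  if (is.null(candidate[["specific_gravity"]]))
    candidate$specific_gravity <- NA_real_
  out <- rbind(as.data.frame(unclass(foods), stringsAsFactors = FALSE),
               candidate[names(foods)])
  validate_foods(out)
  out
}

#' Convert a liquid volume to grams
#'
#' Liquid foods priced by volume are converted to weight at import time using
#' their specific gravity; the optimisation never sees millilitres.
#'
#' @param volume_ml Volume in millilitres.
#' @param sg Specific gravity in g/ml.
#' @return Weight in grams.
#' @export
ml_to_g <- function(volume_ml, sg) {
  if (is.null(sg) || any(is.na(sg)))
    stop("specific gravity required to convert a liquid food to grams")
  if (any(sg <= 0)) stop("specific gravity must be positive")
  volume_ml * sg
}

#' Average cost per 100 g edible portion
#'
#' Each market record contributes one unit cost: the quoted price divided by
#' the mean of its sample weights and by the edible portion factor, scaled to
#' 100 g.  The seasonal cost is the unweighted mean of these per-record unit
#' costs over all traders and markets.
#'
#' @param price Numeric vector of recorded prices (one per trader record).
#' @param sample_weights List (or matrix) of 1-3 as-purchased sample weights
#'   in grams per record; a plain numeric vector is taken as one weight per
#'   record.
#' @param edible_portion_factor The food's edible portion factor.
#' @return Cost per 100 g edible portion (scalar).
#' @export
cost_per_100g_edible <- function(price, sample_weights, edible_portion_factor) {
  if (length(price) == 0L) stop("no price data for food/season")
  if (is.numeric(sample_weights) && !is.list(sample_weights))
    sample_weights <- as.list(sample_weights)
  if (length(sample_weights) != length(price))
    stop("one set of sample weights required per price record")
  if (any(price < 0)) stop("invalid observation: negative price")
  unit <- vapply(seq_along(price), function(i) {
    w <- sample_weights[[i]]
    w <- w[!is.na(w)]
    if (length(w) == 0L || any(w <= 0))
      stop("invalid observation: sample weights must be positive")
    price[i] / (mean(w) * edible_portion_factor) * 100
  }, numeric(1))
  mean(unit)
}

#' Aggregate a price survey into seasonal costs
#'
#' @param prices Data frame with columns `food_id`, `market_id`, `trader_id`,
#'   `season_id`, `price` and `weight1_g` (optionally `weight2_g`,
#'   `weight3_g`).
#' @param foods Validated food table (for edible portion factors).
#' @return Data frame `food_id`, `season_id`, `cost_per_100g_edible`, one row
#'   per food x season observed in the survey.
#' @export
seasonal_prices <- function(prices, foods) {
  required <- c("food_id", "season_id", "price", "weight1_g")
  missing <- setdiff(required, names(prices))
  if (length(missing) > 0L)
    stop("price table is missing columns: ", paste(missing, collapse = ", "))
  if (nrow(prices) == 0L) stop("no price data")
  unknown <- setdiff(unique(prices$food_id), foods$food_id)
  if (length(unknown) > 0L)
    stop("price records for unknown food(s): ",
         paste(unknown, collapse = ", "))
  wcols <- intersect(c("weight1_g", "weight2_g", "weight3_g"), names(prices))
  keys <- unique(prices[c("food_id", "season_id")])
  out <- lapply(seq_len(nrow(keys)), function(k) {
    sel <- prices$food_id == keys$food_id[k] &
      prices$season_id == keys$season_id[k]
    rec <- prices[sel, , drop = FALSE]
    ep <- foods$edible_portion_factor[foods$food_id == keys$food_id[k]]
    weights <- lapply(seq_len(nrow(rec)),
                      function(i) unlist(rec[i, wcols], use.names = FALSE))
    data.frame(
      food_id = keys$food_id[k],
      season_id = keys$season_id[k],
      cost_per_100g_edible =
        cost_per_100g_edible(rec$price, weights, ep),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$season_id, out$food_id), , drop = FALSE]
}

#' Convert an amount between currencies
#'
#' @param amount Amount in the source currency.
#' @param factor Multiplicative conversion rate (target units per source
#'   unit), or a currency code to be looked up in `table`.
#' @param table Optional currency table with columns `code` and
#'   `units_per_reference`.
#' @return Converted amount.
#' @export
convert_currency <- function(amount, factor, table = NULL) {
  if (is.character(factor)) {
    if (is.null(table)) stop("currency table required to look up a code")
    row <- match(factor, table$code)
    if (is.na(row)) stop("unknown currency code: ", factor)
    factor <- table$units_per_reference[row]
  }
  if (!is.numeric(factor) || any(factor <= 0))
    stop("conversion factor must be positive")
  amount * factor
}

#' Read / write the food-table CSV
#'
#' @param path File path of `foods.csv`.
#' @return `read_foods()` returns a validated food table.
#' @export
read_foods <- function(path) {
  validate_foods(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_foods
#' @param foods Validated food table.
#' @export
write_foods <- function(foods, path) {
  utils::write.csv(as.data.frame(unclass(foods)), path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_foods
#' @export
read_prices <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
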