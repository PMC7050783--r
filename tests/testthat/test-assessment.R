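# run the default scenario once per file; assessments are pure functions of
# their inputs so the object can be shared across expectations
sc <- generate_scenario(42)
assessment <- run_assessment(sc)

test_that("annual cost weights weekly season costs by season length", {
  one <- data.frame(name = "year", days = 365L)
  expect_equal(annual_cost(c(year = 70), one), 3650)
  two <- data.frame(name = c("a", "b"), days = c(182L, 183L))
  expect_equal(annual_cost(c(a = 70, b = 70), two), 3650)
  expect_equal(annual_cost(c(a = 0, b = 0), two), 0)
  expect_error(annual_cost(c(a = 70), two), "no weekly cost")
})

test_that("annual cost is invariant to re-partitioning a constant-price year", {
  splits <- list(
    data.frame(name = "all", days = 365L),
    data.frame(name = c("s1", "s2"), days = c(100L, 265L)),
    data.frame(name = paste0("s", 1:5), days = c(73L, 73L, 73L, 73L, 73L)))
  w <- 123.45
  vals <- vapply(splits, function(cal)
    annual_cost(stats::setNames(rep(w, nrow(cal)), cal$name), cal),
    numeric(1))
  expect_equal(vals, rep(w * 365 / 7, 3))
})

test_that("assessment solves every member x season x level and flags nothing", {
  expect_equal(nrow(assessment$costs), 5 * 3 * 4)
  expect_true(all(assessment$costs$status == "optimal"))
  expect_true(all(assessment$annual$all_optimal))
  # weekly household cost is the sum over members
  agg <- stats::aggregate(weekly_cost ~ season + level,
                          data = assessment$costs, FUN = sum)
  merged <- merge(agg, assessment$household_costs,
                  by = c("season", "level"))
  expect_equal(merged$weekly_cost.x, merged$weekly_cost.y)
})

test_that("a household of two identical members costs exactly twice one", {
  duo <- run_assessment(sc, households = list(
    pair = c("adult_man", "adult_man"), solo = "adult_man"),
    levels = "nutritious")
  pair <- duo$household_costs[duo$household_costs$household == "pair", ]
  solo <- duo$household_costs[duo$household_costs$household == "solo", ]
  expect_equal(pair$weekly_cost, 2 * solo$weekly_cost, tolerance = 1e-9)
})

test_that("household aggregation sums edible grams and converts to purchased", {
  season <- sc$seasons$name[1]
  sols <- assessment$solutions$household[[season]]$nutritious
  agg <- aggregate_household(sols, sc$foods)
  expect_equal(agg$weekly_cost,
               sum(vapply(sols, `[[`, numeric(1), "weekly_cost")))
  manual <- Reduce(`+`, lapply(sols, `[[`, "weekly_grams"))
  expect_equal(agg$edible_g[names(manual)], manual)
  ep <- sc$foods$edible_portion_factor[
    match(names(agg$edible_g), sc$foods$food_id)]
  expect_equal(agg$purchased_g, agg$edible_g / ep)
  expect_gte(agg$n_foods, agg$n_groups)
  expect_error(aggregate_household(list(), sc$foods), "must have members")
})

test_that("household union counts foods eaten by any member", {
  a <- structure(list(level = "nutritious", individual = "A",
                      weekly_grams = c(x = 700), weekly_cost = 1),
                 season = "s1", class = "diet_solution")
  b <- structure(list(level = "nutritious", individual = "B",
                      weekly_grams = c(y = 80), weekly_cost = 2),
                 season = "s1", class = "diet_solution")
  foods <- rbind(make_food("x"), make_food("y", "legumes"))
  foods$edible_portion_factor <- c(1, 0.8)
  agg <- aggregate_household(list(a, b), foods)
  expect_equal(agg$n_foods, 2)
  expect_equal(unname(agg$purchased_g["y"]), 100)  # 80 g edible at EP 0.8
  attr(b, "season") <- "s2"
  expect_error(aggregate_household(list(a, b), foods), "across seasons")
})

test_that("override model runs leave the standard diets untouched", {
  before <- assessment$annual$annual_cost
  model <- run_model(assessment, "free_staple",
                     price = data.frame(food_id = "maize_flour",
                                        season_id = NA,
                                        cost_per_100g_edible = 0))
  expect_equal(assessment$annual$annual_cost, before)
  expect_equal(model$name, "free_staple")
  # a free staple can only make diets cheaper
  expect_true(all(model$annual$annual_cost <=
                    assessment$annual$annual_cost + 1e-9))
  expect_error(run_model(assessment, "bad",
                         price = data.frame(food_id = "caviar",
                                            season_id = NA,
                                            cost_per_100g_edible = 1)),
               "unknown food")
})

test_that("zeroing the price of the binding calcium source lowers the nutritious cost", {
  model <- run_model(assessment, "free_fish",
                     price = data.frame(food_id = "dried_fish",
                                        season_id = NA,
                                        cost_per_100g_edible = 0))
  lvl <- assessment$annual$level == "nutritious"
  expect_lt(model$annual$annual_cost[lvl], assessment$annual$annual_cost[lvl])
})

test_that("currency conversion commutes with aggregation", {
  fac <- 0.012
  converted_sum <- convert_currency(sum(assessment$costs$weekly_cost), fac)
  sum_converted <- sum(convert_currency(assessment$costs$weekly_cost, fac))
  expect_equal(converted_sum, sum_converted)
})
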