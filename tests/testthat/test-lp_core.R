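test_that("single-food energy-only problem has the closed-form optimum", {
  ki <- known_optimum_instance("single")
  problem <- diet_problem(ki$foods, ki$prices, ki$individual, ki$level)
  sol <- solve_diet(problem)
  expect_equal(sol$status, "optimal")
  # X = 7 x EAR grams at 1 kcal/g; cost = 7 E c
  expect_equal(sol$weekly_cost, ki$optimal_cost, tolerance = 1e-4)
  expect_equal(unname(sol$weekly_grams), 7 * 2000, tolerance = 1e-4)
  expect_equal(unname(achievement(sol)["energy"]), 100, tolerance = 1e-4)
})

test_that("macronutrient level forces the protein source into the basis", {
  ki <- known_optimum_instance("protein_forcing")
  # at energy-only the cheap starch wins alone
  p_energy <- diet_problem(ki$foods, ki$prices, ki$individual, "energy_only")
  s_energy <- solve_diet(p_energy)
  expect_equal(unname(s_energy$weekly_grams["pulse"]), 0, tolerance = 1e-6)
  # at macronutrients the pulse is bought exactly to the protein requirement
  p_macro <- diet_problem(ki$foods, ki$prices, ki$individual, ki$level)
  s_macro <- solve_diet(p_macro)
  expect_gt(unname(s_macro$weekly_grams["pulse"]), 1000)
  expect_equal(s_macro$weekly_cost, ki$optimal_cost, tolerance = 1e-4)
  bf <- brute_force_diet(p_macro)
  expect_equal(bf$weekly_cost, ki$optimal_cost, tolerance = 1e-4)
})

test_that("degenerate equal-cost duplicates give a unique optimal cost", {
  ki <- known_optimum_instance("tie")
  problem <- diet_problem(ki$foods, ki$prices, ki$individual, ki$level)
  sol <- solve_diet(problem)
  expect_equal(sol$weekly_cost, ki$optimal_cost, tolerance = 1e-4)
  expect_equal(brute_force_diet(problem)$weekly_cost, ki$optimal_cost,
               tolerance = 1e-4)
})

test_that("habit frequencies of zero exclude a food; missing habits are errors", {
  foods <- rbind(make_food("a", energy_kcal = 360, fat_g = 10),
                 make_food("b", "legumes", energy_kcal = 340, fat_g = 10))
  prices <- flat_price(foods, c(1, 2))
  ind <- test_individual()
  habits <- data.frame(food_id = c("a", "b"),
                       min_per_week = c(0, 1), max_per_week = c(0, 21))
  problem <- diet_problem(foods, prices, ind, "food_habits", habits)
  expect_equal(problem$bounds_hi[problem$foods$food_id == "a"], 0)
  sol <- solve_diet(problem)
  if (sol$status == "optimal")
    expect_equal(unname(sol$weekly_grams["a"]), 0, tolerance = 1e-9)
  expect_error(diet_problem(foods, prices, ind, "food_habits"),
               "habit constraints are required")
  expect_error(
    diet_problem(foods, prices, ind, "food_habits", habits[1, ]),
    "no habit frequencies")
})

test_that("group servings ceiling defaults to 105 and foods without prices drop out", {
  foods <- demo_foods()
  prices <- flat_price(foods)
  ind <- demo_individuals()[1, ]
  problem <- diet_problem(foods, prices, ind, "energy_only")
  grp <- grepl("^group:", problem$meta$kind)
  expect_true(all(problem$meta$rhs[grp] == 105))
  expect_equal(sum(grp), length(unique(foods$food_group)))
  expect_warning(
    p2 <- diet_problem(foods, prices[-1, ], ind, "energy_only"),
    "no seasonal price")
  expect_equal(p2$n, nrow(foods) - 1L)
})

test_that("doubling all prices doubles cost and leaves selection unchanged", {
  sc <- generate_scenario(7)
  seasonal <- seasonal_prices(sc$prices, sc$foods)
  ps <- seasonal[seasonal$season_id == "dry", ]
  ind <- sc$individuals[sc$individuals$label == "lactating_woman", ]
  for (level in c("energy_only", "nutritious")) {
    p1 <- diet_problem(sc$foods, ps, ind, level, habits = sc$habits)
    ps2 <- ps
    ps2$cost_per_100g_edible <- 2 * ps2$cost_per_100g_edible
    p2 <- diet_problem(sc$foods, ps2, ind, level, habits = sc$habits)
    s1 <- solve_diet(p1)
    s2 <- solve_diet(p2)
    expect_equal(s2$weekly_cost, 2 * s1$weekly_cost, tolerance = 1e-6)
    expect_equal(s2$weekly_grams, s1$weekly_grams, tolerance = 1e-4)
  }
})

test_that("adding a food never increases the optimal cost", {
  sc <- generate_scenario(11)
  seasonal <- seasonal_prices(sc$prices, sc$foods)
  ps <- seasonal[seasonal$season_id == "lean", ]
  ind <- sc$individuals[sc$individuals$label == "adult_man", ]
  full <- solve_diet(diet_problem(sc$foods, ps, ind, "nutritious"))
  for (drop_id in c("dried_fish", "lentils", "veg_oil")) {
    fewer <- sc$foods[sc$foods$food_id != drop_id, ]
    sub <- solve_diet(diet_problem(
      fewer, ps[ps$food_id != drop_id, ], ind, "nutritious"))
    if (sub$status == "optimal")
      expect_gte(sub$weekly_cost, full$weekly_cost - 1e-6)
  }
})

test_that("optimal solutions satisfy every constraint row", {
  sc <- generate_scenario(42)
  seasonal <- seasonal_prices(sc$prices, sc$foods)
  fam <- sc$individuals[sc$individuals$label != "infant_3m", ]
  for (season in sc$seasons$name) {
    ps <- seasonal[seasonal$season_id == season, ]
    for (i in seq_len(nrow(fam))) {
      problem <- diet_problem(sc$foods, ps, fam[i, ], "food_habits",
                              habits = sc$habits)
      sol <- solve_diet(problem)
      expect_equal(sol$status, "optimal")
      ok <- satisfies_constraints(problem, unname(sol$weekly_grams),
                                  tol = 1e-6)
      expect_true(ok, info = paste(season, fam$label[i], ":",
                                   paste(attr(ok, "violated"),
                                         collapse = ", ")))
    }
  }
})

test_that("solver agrees with the vertex-enumeration oracle on random instances", {
  n_agree <- 0
  for (seed in 1:40) {
    inst <- random_small_instance(seed)
    problem <- diet_problem(inst$foods, inst$prices, inst$individual,
                            inst$level, habits = inst$habits)
    sol <- solve_diet(problem)
    bf <- brute_force_diet(problem)
    expect_equal(sol$status == "optimal", bf$status == "optimal",
                 info = paste("seed", seed))
    if (sol$status == "optimal" && bf$status == "optimal") {
      expect_equal(sol$weekly_cost, bf$weekly_cost,
                   tolerance = 1e-4, info = paste("seed", seed))
      n_agree <- n_agree + 1
    }
  }
  expect_gt(n_agree, 5)  # a healthy share of instances must be feasible
})

test_that("oracle refuses more than three foods", {
  sc <- generate_scenario(3)
  seasonal <- seasonal_prices(sc$prices, sc$foods)
  ps <- seasonal[seasonal$season_id == "dry", ]
  problem <- diet_problem(sc$foods, ps, sc$individuals[1, ], "energy_only")
  expect_error(brute_force_diet(problem), "3 foods")
})

test_that("infeasible problems report infeasible from both routes", {
  # energy requirement unreachable under the total food weight ceiling:
  # a food at 0.5 kcal/g cannot reach EAR grams x 1 kcal/g
  foods <- make_food("thin_gruel", energy_kcal = 50)
  prices <- flat_price(foods)
  ind <- test_individual(ear = 2000, sd = 0)
  problem <- diet_problem(foods, prices, ind, "energy_only")
  expect_equal(solve_diet(problem)$status, "infeasible")
  expect_equal(brute_force_diet(problem)$status, "infeasible")
})

test_that("relaxed solve isolates the unreachable nutrient", {
  # calcium-free market: everything else is reachable
  foods <- rbind(
    make_food("staple", energy_kcal = 360, protein_g = 10, fat_g = 4,
              vitamin_a_ug_re = 500, vitamin_c_mg = 50, vitamin_b1_mg = 1,
              vitamin_b2_mg = 1, niacin_mg = 5, vitamin_b6_mg = 1,
              folic_acid_ug = 300, vitamin_b12_ug = 2,
              pantothenic_acid_mg = 4, iron_mg = 3, magnesium_mg = 200,
              zinc_mg = 6),
    make_food("oil", "oils and fats", energy_kcal = 884, fat_g = 100))
  prices <- flat_price(foods)
  ind <- test_individual(ear = 2000, sd = 200, fat_min = 20, fat_max = 35)
  problem <- diet_problem(foods, prices, ind, "nutritious")
  expect_equal(solve_diet(problem)$status, "infeasible")
  rel <- relaxed_solve(problem)
  expect_equal(rel$status, "relaxed")
  ach <- achievement(rel)
  expect_lt(ach[["calcium"]], 100)
  others <- setdiff(names(ach), c("calcium", "fat"))
  expect_true(all(ach[others] >= 100 - 1e-4, na.rm = TRUE))
  expect_true("calcium" %in% names(rel$shortfall))
})

test_that("relaxed solve on a feasible problem reproduces the optimum", {
  ki <- known_optimum_instance("protein_forcing")
  problem <- diet_problem(ki$foods, ki$prices, ki$individual, ki$level)
  rel <- relaxed_solve(problem)
  expect_equal(rel$status, "optimal")
  expect_equal(rel$weekly_cost, ki$optimal_cost, tolerance = 1e-4)
})

test_that("achievement marks binding nutrients at exactly 100", {
  ki <- known_optimum_instance("protein_forcing")
  problem <- diet_problem(ki$foods, ki$prices, ki$individual, ki$level)
  sol <- solve_diet(problem)
  ach <- achievement(sol)
  expect_equal(unname(ach["energy"]), 100, tolerance = 1e-4)
  expect_equal(unname(ach["protein"]), 100, tolerance = 1e-4)  # binding
  # over-supply above 100 is allowed for nutrients without upper limits
  sc <- generate_scenario(42)
  seasonal <- seasonal_prices(sc$prices, sc$foods)
  sol2 <- solve_diet(diet_problem(
    sc$foods, seasonal[seasonal$season_id == "lean", ],
    sc$individuals[sc$individuals$label == "adult_man", ], "nutritious"))
  expect_gt(max(achievement(sol2), na.rm = TRUE), 100)
})

test_that("diet costs are monotone over the nested levels", {
  sc <- generate_scenario(42)
  seasonal <- seasonal_prices(sc$prices, sc$foods)
  fam <- sc$individuals[sc$individuals$label != "infant_3m", ]
  for (season in sc$seasons$name) {
    ps <- seasonal[seasonal$season_id == season, ]
    for (i in seq_len(nrow(fam))) {
      costs <- vapply(diet_levels(), function(level)
        solve_diet(diet_problem(sc$foods, ps, fam[i, ], level,
                                habits = sc$habits))$weekly_cost,
        numeric(1))
      expect_true(all(diff(costs) >= -1e-6),
                  info = paste(season, fam$label[i]))
    }
  }
})

test_that("solutions are reproducible given identical inputs", {
  sc <- generate_scenario(42)
  seasonal <- seasonal_prices(sc$prices, sc$foods)
  ps <- seasonal[seasonal$season_id == "dry", ]
  ind <- sc$individuals[1, ]
  s1 <- solve_diet(diet_problem(sc$foods, ps, ind, "nutritious"))
  s2 <- solve_diet(diet_problem(sc$foods, ps, ind, "nutritious"))
  expect_identical(s1$weekly_grams, s2$weekly_grams)
  expect_identical(s1$weekly_cost, s2$weekly_cost)
})
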