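test_that("energy specification follows the normal percentile model", {
  ind <- test_individual(ear = 2000, sd = 200)
  expect_equal(energy_at_percentile(ind, 50), 2000)          # z(50) = 0
  expect_equal(energy_at_percentile(ind, 97.725), 2400, tolerance = 1e-5)
  expect_equal(energy_at_percentile(ind, 84.134), 2199.996077,
               tolerance = 1e-6)
  # strictly increasing in p for sd > 0
  ps <- seq(1, 99, by = 7)
  vals <- vapply(ps, function(p) energy_at_percentile(ind, p), numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_error(energy_at_percentile(ind, 0.5), "between 1 and 99")
  expect_error(energy_at_percentile(ind, 100), "between 1 and 99")
})

test_that("protein specification is the 95th percentile per kg times weight", {
  ind <- test_individual(weight = 60, protein_mean = 0.66,
                         protein_sd = 0.0825)
  expect_equal(protein_spec(ind, 95), 47.742025, tolerance = 1e-6)
  expect_equal(protein_spec(ind, 50), 0.66 * 60)
  degenerate <- test_individual(weight = 0, protein_mean = 0.66,
                                protein_sd = 0.0825)
  expect_equal(protein_spec(degenerate, 95), 0)
  infant <- demo_individuals()[demo_individuals()$label == "infant_3m", ]
  expect_error(protein_spec(infant, 95), ">12 months")
})

test_that("infant protein follows the breast-milk energy density rule", {
  infant <- demo_individuals()[demo_individuals()$label == "infant_3m", ]
  # EAR 500 kcal at 0.67 kcal/ml -> 746.27 ml of milk
  expect_equal(infant_protein_spec(infant, protein_per_ml = 0.011),
               8.208955, tolerance = 1e-6)
  tiny <- infant
  tiny$energy_ear_kcal <- 0.67  # exactly 1 ml worth
  expect_equal(infant_protein_spec(tiny, protein_per_ml = 0.011), 0.011)
  bm <- make_food("breast_milk", "breast milk", protein_g = 1.1)
  bm$specific_gravity <- 1.0  # 1.1 g/100 ml
  expect_equal(infant_protein_spec(infant, breast_milk = bm),
               500 / 0.67 * 0.011, tolerance = 1e-9)
  expect_error(infant_protein_spec(infant), "breast-milk composition")
})

test_that("fat bounds convert energy percentages at 9 kcal/g", {
  ind <- test_individual(ear = 2000, fat_min = 20, fat_max = 35)
  b <- fat_bounds_g(ind)
  expect_equal(unname(b["min"]), 44.444444, tolerance = 1e-6)
  expect_equal(unname(b["max"]), 77.777778, tolerance = 1e-6)
  # zero-width band accepted
  z <- fat_bounds_g(ind, pct_min = 30, pct_max = 30)
  expect_equal(unname(z["min"]), unname(z["max"]))
  expect_error(fat_bounds_g(ind, pct_min = 0.5), "between 1 and 99")
})

test_that("micronutrient percentiles centre on RNI minus two SD", {
  ind <- demo_individuals()[demo_individuals()$label == "adult_man", ]
  rni <- ind$rni_calcium
  sd <- ind$rni_sd_calcium
  expect_equal(micronutrient_at_percentile(ind, "calcium", 97.725), rni,
               tolerance = 1e-6)
  expect_equal(micronutrient_at_percentile(ind, "calcium", 50),
               rni - 2 * sd, tolerance = 1e-9)
  expect_error(micronutrient_at_percentile(ind, "pantothenic_acid", 50),
               "no adjustment factors")
  expect_error(micronutrient_at_percentile(ind, "magnesium", 50),
               "no adjustment factors")
  expect_error(micronutrient_at_percentile(ind, "vitamin_a", 50),
               "safe intake")
  infant <- demo_individuals()[demo_individuals()$label == "infant_3m", ]
  expect_error(micronutrient_at_percentile(infant, "calcium", 50),
               ">12 months")
})

test_that("zinc specification selects the bioavailability level", {
  ind <- demo_individuals()[demo_individuals()$label == "adult_man", ]
  expect_equal(zinc_spec(ind), ind$zinc_rni_moderate_mg)  # default moderate
  expect_equal(zinc_spec(ind, "low"), ind$zinc_rni_low_mg)
  expect_gte(zinc_spec(ind, "low"), zinc_spec(ind, "moderate"))
  expect_gte(zinc_spec(ind, "moderate"), zinc_spec(ind, "high"))
  expect_error(zinc_spec(ind, "none"))
})

test_that("switching zinc bioavailability changes only the zinc constraint", {
  foods <- demo_foods()
  prices <- flat_price(foods)
  ind <- demo_individuals()[1, ]
  p_mod <- diet_problem(foods, prices, ind, "nutritious",
                        config = diet_config(zinc_bioavailability =
                                               "moderate"))
  p_low <- diet_problem(foods, prices, ind, "nutritious",
                        config = diet_config(zinc_bioavailability = "low"))
  differs <- p_mod$meta$rhs != p_low$meta$rhs
  expect_identical(p_mod$meta$kind[differs], "micro_lo:zinc")
  expect_identical(p_mod$A, p_low$A)
})

test_that("portion sizes scale with mean + 2 SD energy from the reference child", {
  child_ref_energy <- 1000
  ind <- test_individual(ear = 2100, sd = 210)
  expect_equal(portion_scaling_factor(ind, child_ref_energy), 2.52)
  ref_like <- test_individual(ear = 1000, sd = 0)
  expect_equal(portion_scaling_factor(ref_like, child_ref_energy), 1.0)
  scheme <- portion_scheme(reference_energy_kcal = child_ref_energy)
  expect_equal(portion_size(ind, "legumes", scheme),
               scheme$child_portions_g[["legumes"]] * 2.52)
  expect_equal(portion_size(ref_like, "legumes", scheme),
               scheme$child_portions_g[["legumes"]])
  # exception groups keep their fixed portion for everyone
  expect_equal(portion_size(ind, "condiments", scheme),
               scheme$fixed_portions_g[["condiments"]])
  expect_error(portion_size(ind, "unknown group", scheme), "no portion")
  # monotone in energy, never negative
  ears <- seq(500, 4000, by = 500)
  f <- vapply(ears, function(e)
    portion_scaling_factor(test_individual(ear = e, sd = 0.1 * e)),
    numeric(1))
  expect_true(all(diff(f) > 0) && all(f > 0))
})

test_that("total food weight limit is mean + 2 SD energy over 1 kcal/g", {
  expect_equal(total_food_weight_limit(test_individual(ear = 2000, sd = 200)),
               2400)
  expect_equal(total_food_weight_limit(test_individual(ear = 1000, sd = 0)),
               1000)
  ind <- test_individual(ear = 1800, sd = 90)
  expect_gt(total_food_weight_limit(ind), ind$energy_ear_kcal)
})

test_that("season calendars must cover exactly 365 days", {
  ok <- data.frame(name = "year", days = 365L)
  expect_silent(validate_calendar(ok))
  ok3 <- data.frame(name = c("a", "b", "c"), days = c(100L, 100L, 165L))
  expect_silent(validate_calendar(ok3))
  expect_error(validate_calendar(
    data.frame(name = c("a", "b"), days = c(180L, 180L))), "deficit 5")
  expect_error(validate_calendar(
    data.frame(name = letters[1:7], days = rep(52L, 7))), "1 and 6")
})

test_that("standard families align to 2,100 kcal/person with required members", {
  fam <- demo_individuals()[demo_individuals()$label != "infant_3m", ]
  sf <- standard_family(fam)
  expect_equal(sf$mean_ear_kcal, 2100)
  # dropping the toddler breaks composition
  expect_error(standard_family(
    fam[fam$label != "child_12_23m", ], tolerance = 0.3), "12-23 months")
  # far-off mean fails the alignment tolerance
  heavy <- fam
  heavy$energy_ear_kcal <- heavy$energy_ear_kcal * 1.5
  expect_error(standard_family(heavy), "not within 2%")
})

test_that("individuals table round-trips and validates", {
  ind <- demo_individuals()
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(ind, path, row.names = FALSE)
  back <- read_individuals(path)
  expect_equal(back$rni_calcium, ind$rni_calcium)
  bad <- ind
  bad$zinc_rni_high_mg[1] <- 99
  expect_error(validate_individuals(bad), "zinc")
  bad2 <- ind
  bad2$ul_calcium[1] <- 10
  expect_error(validate_individuals(bad2), "upper limit")
})
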