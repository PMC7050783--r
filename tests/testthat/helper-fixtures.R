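# Fixtures built in code: a minimal blank food row, simple named foods and a
# dispersion-free test individual, so constraint arithmetic is checkable by
# hand.

blank_food <- function(id = "food", group = "staples") {
  f <- demo_foods()[1, ]
  for (col in nutrient_registry()$food_column) f[[col]] <- 0
  f$food_id <- id
  f$name <- id
  f$food_group <- group
  f$edible_portion_factor <- 1
  f$specific_gravity <- NA_real_
  f$iron_absorption_factor <- 1
  rownames(f) <- NULL
  f
}

make_food <- function(id, group = "staples", ...) {
  f <- blank_food(id, group)
  vals <- list(...)
  for (nm in names(vals)) f[[nm]] <- vals[[nm]]
  f
}

# adult with round numbers and zero dispersion unless asked for
test_individual <- function(ear = 2000, sd = 0, weight = 60,
                            protein_mean = 0.75, protein_sd = 0,
                            fat_min = 1, fat_max = 35) {
  ind <- demo_individuals()[demo_individuals()$label == "adult_man", ]
  ind$energy_ear_kcal <- ear
  ind$energy_sd_kcal <- sd
  ind$body_weight_kg <- weight
  ind$protein_g_per_kg_mean <- protein_mean
  ind$protein_g_per_kg_sd <- protein_sd
  ind$fat_pct_min <- fat_min
  ind$fat_pct_max <- fat_max
  rownames(ind) <- NULL
  ind
}

flat_price <- function(foods, cost_per_100g = 1) {
  data.frame(food_id = foods$food_id,
             cost_per_100g_edible = rep_len(cost_per_100g, nrow(foods)))
}
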