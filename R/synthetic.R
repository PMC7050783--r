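# Synthetic market scenarios: a small multi-season market with staple,
# legume, vegetable, animal-source, oil, dairy, fruit and condiment
# archetypes, plus the individuals, habits, calendar and wealth groups needed
# for a complete assessment.  All numbers are synthetic: archetype nutrient
# profiles are plausible for their food class but are not food-table truth,
# and prices emulate no real country's level.

#' @noRd
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Synthetic food archetypes
#'
#' Eleven foods spanning the archetypes of a rural market: two staples,
#' two legumes, a green leafy vegetable, small dried fish, vegetable oil,
#' fresh cow milk, a fruit, eggs and salt.  Composition per 100 g edible
#' portion.
#'
#' @return A validated food table.
#' @export
demo_foods <- function() {
  f <- data.frame(
    food_id = c("maize_flour", "rice", "lentils", "groundnut",
                "amaranth_leaves", "dried_fish", "veg_oil", "cow_milk",
                "banana", "eggs", "salt"),
    name = c("Maize flour", "Rice", "Lentils", "Groundnut",
             "Amaranth leaves", "Small dried fish", "Vegetable oil",
             "Cow milk (fresh)", "Banana", "Hen eggs", "Salt"),
    food_group = c("staples", "staples", "legumes", "legumes", "vegetables",
                   "fish", "oils and fats", "milk and dairy", "fruits",
                   "eggs", "condiments"),
    energy_kcal = c(360, 355, 340, 567, 30, 300, 884, 62, 90, 140, 0),
    protein_g = c(9, 7, 24, 26, 3, 60, 0, 3.3, 1.1, 12.5, 0),
    fat_g = c(4, 1, 1.5, 49, 0.3, 6, 100, 3.5, 0.3, 10, 0),
    vitamin_a_ug_re = c(0, 0, 2, 0, 400, 30, 0, 35, 3, 140, 0),
    vitamin_c_mg = c(0, 0, 2, 0, 45, 0, 0, 1, 9, 0, 0),
    vitamin_b1_mg = c(0.35, 0.2, 0.9, 0.6, 0.03, 0.1, 0, 0.04, 0.03,
                      0.07, 0),
    vitamin_b2_mg = c(0.12, 0.05, 0.25, 0.14, 0.2, 0.5, 0, 0.18, 0.07,
                      0.45, 0),
    niacin_mg = c(2, 1.8, 2.5, 13.5, 0.7, 10, 0, 0.1, 0.6, 0.07, 0),
    vitamin_b6_mg = c(0.3, 0.15, 0.5, 0.35, 0.2, 0.4, 0, 0.04, 0.35,
                      0.12, 0),
    folic_acid_ug = c(25, 10, 480, 240, 85, 25, 0, 5, 20, 47, 0),
    vitamin_b12_ug = c(0, 0, 0, 0, 0, 9, 0, 0.45, 0, 0.9, 0),
    pantothenic_acid_mg = c(0.6, 1, 2.1, 1.8, 0.06, 1, 0, 0.35, 0.35,
                            1.5, 0),
    calcium_mg = c(10, 8, 60, 90, 215, 2000, 0, 115, 5, 50, 0),
    iron_mg = c(2.5, 1, 7.5, 2.5, 2.3, 9, 0, 0.05, 0.3, 1.8, 0),
    magnesium_mg = c(100, 35, 120, 168, 55, 150, 0, 10, 27, 12, 0),
    zinc_mg = c(1.8, 1.2, 3.9, 3.3, 0.9, 7, 0, 0.4, 0.15, 1.3, 0),
    edible_portion_factor = c(1, 1, 1, 0.7, 0.7, 0.9, 1, 1, 0.65, 0.88, 1),
    specific_gravity = c(NA, NA, NA, NA, NA, NA, 0.92, 1.03, NA, NA, NA),
    iron_absorption_factor = c(0.05, 0.05, 0.05, 0.05, 0.07, 0.12, 1,
                               0.1, 0.05, 0.12, 1),
    stringsAsFactors = FALSE
  )
  validate_foods(f)
  f
}

#' Synthetic individuals table
#'
#' Six WHO/FAO-style specification rows: the five members of the shipped
#' standard family (whose mean energy EAR is exactly 2,100 kcal/person) and a
#' breast-fed infant used only for the infant protein rule.  Micronutrient
#' dispersions are modelled with SD = 0.1 x RNI (equivalent to a CV of 12.5%
#' of the mean requirement, since the RNI sits 2 SD above the mean); these
#' defaults are editable data, not constants.
#'
#' @return A validated individuals table.
#' @export
demo_individuals <- function() {
  rni <- function(vitamin_a, vitamin_c, vitamin_b1, vitamin_b2, niacin,
                  vitamin_b6, folic_acid, vitamin_b12, pantothenic_acid,
                  calcium, iron, magnesium, zinc) {
    c(vitamin_a = vitamin_a, vitamin_c = vitamin_c, vitamin_b1 = vitamin_b1,
      vitamin_b2 = vitamin_b2, niacin = niacin, vitamin_b6 = vitamin_b6,
      folic_acid = folic_acid, vitamin_b12 = vitamin_b12,
      pantothenic_acid = pantothenic_acid, calcium = calcium, iron = iron,
      magnesium = magnesium, zinc = zinc)
  }
  rows <- list(
    list(label = "adult_man", age_months = 360, sex = "m",
         is_lactating = FALSE, body_weight_kg = 60,
         energy_ear_kcal = 2900, protein = c(0.66, 0.0825), fat = c(20, 35),
         rni = rni(600, 45, 1.2, 1.3, 16, 1.3, 400, 2.4, 5, 1000, 1.14,
                   260, 7),
         ul = c(3000, 1000, 35, 2500, 45), zinc3 = c(14, 7, 4.2)),
    list(label = "lactating_woman", age_months = 300, sex = "f",
         is_lactating = TRUE, body_weight_kg = 55,
         energy_ear_kcal = 2850, protein = c(0.7, 0.0875), fat = c(20, 35),
         rni = rni(850, 70, 1.5, 1.6, 17, 2.0, 500, 2.8, 7, 1000, 1.31,
                   270, 9.5),
         ul = c(3000, 1000, 35, 2500, 45), zinc3 = c(19, 9.5, 5.8)),
    list(label = "child_12_23m", age_months = 18, sex = "f",
         is_lactating = FALSE, body_weight_kg = 10,
         energy_ear_kcal = 900, protein = c(0.86, 0.1075), fat = c(30, 45),
         rni = rni(400, 30, 0.5, 0.5, 6, 0.5, 150, 0.9, 2, 500, 0.58,
                   60, 4.1),
         ul = c(600, 400, 10, 2500, 40), zinc3 = c(8.3, 4.1, 2.4)),
    list(label = "child_6_7y", age_months = 78, sex = "m",
         is_lactating = FALSE, body_weight_kg = 21,
         energy_ear_kcal = 1750, protein = c(0.76, 0.095), fat = c(25, 35),
         rni = rni(500, 30, 0.9, 0.9, 12, 1.0, 200, 1.8, 4, 600, 0.87,
                   100, 4.8),
         ul = c(900, 650, 15, 2500, 40), zinc3 = c(9.6, 4.8, 3.1)),
    list(label = "boy_10_11y", age_months = 126, sex = "m",
         is_lactating = FALSE, body_weight_kg = 32,
         energy_ear_kcal = 2100, protein = c(0.75, 0.094), fat = c(25, 35),
         rni = rni(600, 40, 1.0, 1.2, 14, 1.2, 300, 2.2, 5, 1300, 1.05,
                   220, 5.6),
         ul = c(1700, 1200, 20, 2500, 40), zinc3 = c(11.2, 5.6, 3.4)),
    list(label = "infant_3m", age_months = 3, sex = "f",
         is_lactating = FALSE, body_weight_kg = 6,
         energy_ear_kcal = 500, protein = c(1.31, 0), fat = c(30, 60),
         rni = rni(375, 25, 0.2, 0.3, 2, 0.1, 80, 0.4, 1.7, 300, 0.3,
                   26, 2.8),
         ul = c(600, 300, 4, 1500, 40), zinc3 = c(6.6, 2.8, 1.1))
  )
  sd_micros <- nutrient_registry()$key[nutrient_registry()$percentile_adjustable]
  out <- lapply(rows, function(r) {
    d <- data.frame(label = r$label, age_months = r$age_months, sex = r$sex,
                    is_lactating = r$is_lactating,
                    body_weight_kg = r$body_weight_kg,
                    energy_ear_kcal = r$energy_ear_kcal,
                    energy_sd_kcal = 0.1 * r$energy_ear_kcal,
                    protein_g_per_kg_mean = r$protein[1],
                    protein_g_per_kg_sd = r$protein[2],
                    fat_pct_min = r$fat[1], fat_pct_max = r$fat[2],
                    stringsAsFactors = FALSE)
    for (m in names(r$rni)) d[[paste0("rni_", m)]] <- unname(r$rni[m])
    for (m in sd_micros) d[[paste0("rni_sd_", m)]] <- 0.1 * unname(r$rni[m])
    uln <- paste0("ul_", upper_limit_keys())
    for (i in seq_along(uln)) d[[uln[i]]] <- r$ul[i]
    d$zinc_rni_low_mg <- r$zinc3[1]
    d$zinc_rni_moderate_mg <- r$zinc3[2]
    d$zinc_rni_high_mg <- r$zinc3[3]
    d$rni_zinc <- r$zinc3[2]  # moderate is the default level
    d
  })
  out <- do.call(rbind, out)
  validate_individuals(out)
  out
}

#' @noRd
demo_base_prices <- function() {
  # price per typical sale unit; weights in grams as purchased
  data.frame(
    food_id = c("maize_flour", "rice", "lentils", "groundnut",
                "amaranth_leaves", "dried_fish", "veg_oil", "cow_milk",
                "banana", "eggs", "salt"),
    unit_weight_g = c(1000, 1000, 500, 500, 400, 100, 500, 515, 600, 360,
                      500),
    unit_price = c(40, 60, 60, 75, 20, 40, 90, 41, 36, 90, 10),
    stringsAsFactors = FALSE
  )
}

#' @noRd
demo_season_multipliers <- function() {
  mult <- rbind(
    post_harvest = c(maize_flour = 0.85, rice = 0.9, lentils = 0.9,
                     groundnut = 0.9, amaranth_leaves = 1.2, dried_fish = 1.0,
                     veg_oil = 1.0, cow_milk = 1.0, banana = 1.0, eggs = 1.0,
                     salt = 1.0),
    dry = c(maize_flour = 1.0, rice = 1.0, lentils = 1.0, groundnut = 1.05,
            amaranth_leaves = 0.8, dried_fish = 0.9, veg_oil = 1.0,
            cow_milk = 1.1, banana = 0.9, eggs = 1.0, salt = 1.0),
    lean = c(maize_flour = 1.35, rice = 1.25, lentils = 1.2, groundnut = 1.2,
             amaranth_leaves = 1.4, dried_fish = 1.1, veg_oil = 1.05,
             cow_milk = 1.2, banana = 1.1, eggs = 1.1, salt = 1.0)
  )
  mult
}

#' Synthetic season calendar, habits, wealth groups and currencies
#'
#' @return Data frames in the respective input schemas.
#' @export
demo_seasons <- function() {
  data.frame(name = c("post_harvest", "dry", "lean"),
             days = c(120L, 120L, 125L), stringsAsFactors = FALSE)
}

#' @rdname demo_seasons
#' @export
demo_habits <- function() {
  data.frame(
    food_id = c("maize_flour", "rice", "lentils", "groundnut",
                "amaranth_leaves", "dried_fish", "veg_oil", "cow_milk",
                "banana", "eggs", "salt"),
    min_per_week = c(7, 0, 3, 0, 3, 1, 7, 0, 0, 0, 7),
    max_per_week = c(21, 14, 14, 7, 14, 7, 21, 14, 7, 7, 21),
    stringsAsFactors = FALSE
  )
}

#' @rdname demo_seasons
#' @export
demo_wealth_groups <- function() {
  data.frame(
    name = c("very poor", "poor", "middle", "better-off"),
    annual_income = c(30000, 50000, 90000, 160000),
    annual_nonfood_expenditure = c(12000, 18000, 30000, 45000),
    stringsAsFactors = FALSE
  )
}

#' @rdname demo_seasons
#' @export
demo_currencies <- function() {
  data.frame(code = c("LCU", "USD", "EUR"),
             units_per_reference = c(1, 0.012, 0.011),
             stringsAsFactors = FALSE)
}

#' Construct a designed feasible weekly diet for one individual
#'
#' A certificate of feasibility for the nutritious level, built without the
#' LP solver: start from a fixed energy-share template over the archetypes,
#' then greedily repair any nutrient shortfall by adding the densest source
#' and rebalancing staple energy, and finally check every constraint row.
#'
#' @param foods Validated food table.
#' @param prices Seasonal costs for one season (`food_id`,
#'   `cost_per_100g_edible`).
#' @param ind One individual.
#' @param config A [diet_config()].
#' @return Named vector of weekly grams, or `NULL` with attribute
#'   `"violated"` naming the first unrepairable nutrient.
#' @export
designed_diet <- function(foods, prices, ind, config = diet_config()) {
  problem <- diet_problem(foods, prices, ind, level = "nutritious",
                          config = config)
  f <- problem$foods
  n <- problem$n
  energy_per_g <- problem$nut_per_g["energy", ]
  target <- problem$specs$energy
  shares <- c(maize_flour = 0.40, rice = 0.10, lentils = 0.10,
              groundnut = 0.06, veg_oil = 0.10, cow_milk = 0.06,
              dried_fish = 0.05, eggs = 0.04, banana = 0.03,
              amaranth_leaves = 0.03)
  x <- stats::setNames(numeric(n), f$food_id)
  for (id in intersect(names(shares), f$food_id))
    x[id] <- shares[[id]] * target / energy_per_g[f$food_id == id]
  x <- x * target / sum(energy_per_g * x)  # exact energy

  staple <- which.max(ifelse(f$food_group == "staples", energy_per_g, -Inf))
  lower <- problem$meta$dir == ">=" & !problem$meta$kind %in% "energy_lo"
  for (iter in seq_len(100)) {
    lhs <- drop(problem$A %*% x)
    gap <- problem$meta$rhs - lhs
    viol <- which(lower & gap > 1e-9 * pmax(problem$meta$rhs, 1))
    if (length(viol) == 0L) break
    k <- viol[which.max(gap[viol] / pmax(problem$meta$rhs[viol], 1e-12))]
    coefs <- problem$A[k, ]
    # densest source per unit energy keeps the rebalance cheap
    score <- coefs / pmax(energy_per_g, 1e-9)
    score[staple] <- -Inf
    j <- which.max(score)
    if (coefs[j] <= 0) {
      out <- NULL
      attr(out, "violated") <- problem$meta$nutrient[k]
      return(out)
    }
    add <- gap[k] / coefs[j] * 1.05
    x[j] <- x[j] + add
    x[staple] <- x[staple] - add * energy_per_g[j] / energy_per_g[staple]
    if (x[staple] < 0) {
      out <- NULL
      attr(out, "violated") <- problem$meta$nutrient[k]
      return(out)
    }
  }
  ok <- satisfies_constraints(problem, unname(x), tol = 1e-6)
  if (!ok) {
    out <- NULL
    attr(out, "violated") <- paste(attr(ok, "violated"), collapse = ", ")
    return(out)
  }
  x
}

#' Generate a complete synthetic assessment scenario
#'
#' Emits the full input set (foods, market price records, habits,
#' individuals, seasons, wealth groups, currencies) for a small three-market
#' economy, reproducibly from a seed.  For the default preset a designed
#' feasible diet is constructed for every family member before the scenario
#' is returned; generation refuses, naming the violated nutrient, if the
#' archetypes cannot reach feasibility.
#'
#' @param seed Integer seed; the whole scenario is a deterministic function
#'   of it.
#' @param preset `"default"`; `"infeasible-calcium"` removes the dried fish,
#'   milk and egg archetypes and substitutes a calcium-poor leaf variety so
#'   the nutritious diet cannot meet calcium; `"single-season"` collapses the
#'   calendar to one 365-day season.
#' @param n_markets,n_traders Market survey size.
#' @param price_noise_sd,weight_noise_sd Lognormal SD of trader price and
#'   sample weight variation.
#' @return A `diet_scenario` list of tables: `foods`, `prices`, `habits`,
#'   `individuals`, `seasons`, `wealth_groups`, `currencies`, plus the
#'   `certificates` attribute for the default preset.
#' @export
generate_scenario <- function(seed = 42,
                              preset = c("default", "infeasible-calcium",
                                         "single-season"),
                              n_markets = 3, n_traders = 2,
                              price_noise_sd = 0.08,
                              weight_noise_sd = 0.03) {
  preset <- match.arg(preset)
  foods <- demo_foods()
  seasons <- demo_seasons()
  mult <- demo_season_multipliers()
  if (preset == "infeasible-calcium") {
    foods <- foods[!foods$food_id %in%
                     c("dried_fish", "cow_milk", "eggs"), , drop = FALSE]
    foods$calcium_mg[foods$food_id == "amaranth_leaves"] <- 40
    foods$name[foods$food_id == "amaranth_leaves"] <-
      "Amaranth leaves (calcium-poor)"
    validate_foods(foods)
  }
  if (preset == "single-season") {
    seasons <- data.frame(name = "year_round", days = 365L,
                          stringsAsFactors = FALSE)
    mult <- rbind(year_round = colMeans(mult))
  }
  validate_calendar(seasons)
  base <- demo_base_prices()
  base <- base[base$food_id %in% foods$food_id, , drop = FALSE]

  prices <- local_seed(seed, {
    rows <- expand.grid(food_id = base$food_id, season_id = seasons$name,
                        market_id = paste0("market_", seq_len(n_markets)),
                        trader_id = paste0("trader_", seq_len(n_traders)),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    rows <- rows[order(rows$food_id, rows$season_id, rows$market_id,
                       rows$trader_id), , drop = FALSE]
    b <- base[match(rows$food_id, base$food_id), ]
    m <- mult[cbind(rows$season_id, rows$food_id)]
    k <- nrow(rows)
    price <- b$unit_price * m * exp(stats::rnorm(k, 0, price_noise_sd))
    w <- matrix(exp(stats::rnorm(3 * k, 0, weight_noise_sd)), k, 3) *
      b$unit_weight_g
    data.frame(rows,
               price = round(price, 2),
               weight1_g = round(w[, 1]), weight2_g = round(w[, 2]),
               weight3_g = round(w[, 3]), stringsAsFactors = FALSE)
  })

  habits <- demo_habits()
  habits <- habits[habits$food_id %in% foods$food_id, , drop = FALSE]
  scenario <- structure(list(
    foods = foods, prices = prices, habits = habits,
    individuals = demo_individuals(), seasons = seasons,
    wealth_groups = demo_wealth_groups(), currencies = demo_currencies(),
    preset = preset, seed = seed
  ), class = "diet_scenario")

  if (preset != "infeasible-calcium") {
    seasonal <- seasonal_prices(prices, foods)
    family <- scenario$individuals[scenario$individuals$label != "infant_3m",
                                   , drop = FALSE]
    certificates <- list()
    for (s in seasons$name) {
      ps <- seasonal[seasonal$season_id == s, , drop = FALSE]
      for (i in seq_len(nrow(family))) {
        d <- designed_diet(foods, ps, family[i, ])
        if (is.null(d))
          stop("archetype set cannot reach feasibility for ",
               family$label[i], " in season ", s, "; violated nutrient: ",
               attr(d, "violated"))
        certificates[[paste(s, family$label[i], sep = "/")]] <- d
      }
    }
    attr(scenario, "certificates") <- certificates
  }
  scenario
}

#' Write / read a scenario as a directory of CSV (and YAML) files
#'
#' @param scenario A `diet_scenario`.
#' @param dir Directory path.
#' @return `write_scenario()` the directory, invisibly; `read_scenario()` a
#'   `diet_scenario`.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.data.frame(unclass(scenario$foods)),
                   file.path(dir, "foods.csv"), row.names = FALSE)
  utils::write.csv(scenario$prices, file.path(dir, "prices.csv"),
                   row.names = FALSE)
  utils::write.csv(scenario$habits, file.path(dir, "habits.csv"),
                   row.names = FALSE)
  utils::write.csv(scenario$individuals, file.path(dir, "individuals.csv"),
                   row.names = FALSE)
  utils::write.csv(scenario$seasons, file.path(dir, "seasons.csv"),
                   row.names = FALSE)
  utils::write.csv(scenario$wealth_groups,
                   file.path(dir, "wealth_groups.csv"), row.names = FALSE)
  utils::write.csv(scenario$currencies, file.path(dir, "currencies.csv"),
                   row.names = FALSE)
  fam <- scenario$individuals$label[scenario$individuals$label != "infant_3m"]
  yaml::write_yaml(list(standard_family = as.list(fam)),
                   file.path(dir, "households.yaml"))
  invisible(dir)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(dir) {
  structure(list(
    foods = read_foods(file.path(dir, "foods.csv")),
    prices = read_prices(file.path(dir, "prices.csv")),
    habits = utils::read.csv(file.path(dir, "habits.csv"),
                             stringsAsFactors = FALSE),
    individuals = read_individuals(file.path(dir, "individuals.csv")),
    seasons = read_seasons(file.path(dir, "seasons.csv")),
    wealth_groups = utils::read.csv(file.path(dir, "wealth_groups.csv"),
                                    stringsAsFactors = FALSE),
    currencies = utils::read.csv(file.path(dir, "currencies.csv"),
                                 stringsAsFactors = FALSE)
  ), class = "diet_scenario")
}

#' Small problem instances with independently known optima
#'
#' Feeds for verifying the solver: the optimal cost of each instance is
#' computed here by closed form, never by the LP code.
#'
#' @param kind `"single"` (one food, energy-only: the optimum is all energy
#'   from that food), `"protein_forcing"` (cheap pure-starch food plus a
#'   dearer protein source; the macronutrients level must buy the protein
#'   food exactly to its requirement) or `"tie"` (two identical equal-cost
#'   foods: any split is optimal and the cost is unique).
#' @return List with `foods`, `prices`, `individual`, `level`, `config` and
#'   `optimal_cost` (weekly, closed form).
#' @export
known_optimum_instance <- function(kind = c("single", "protein_forcing",
                                            "tie")) {
  kind <- match.arg(kind)
  blank <- demo_foods()[1, ]
  for (col in food_nutrient_columns()) blank[[col]] <- 0
  blank$edible_portion_factor <- 1
  blank$iron_absorption_factor <- 1
  blank$specific_gravity <- NA_real_
  mkfood <- function(id, group, energy, protein = 0, fat = 0) {
    f <- blank
    f$food_id <- id
    f$name <- id
    f$food_group <- group
    f$energy_kcal <- energy
    f$protein_g <- protein
    f$fat_g <- fat
    f
  }
  ind <- demo_individuals()[1, ]
  ind$energy_ear_kcal <- 2000
  ind$energy_sd_kcal <- 0
  ind$protein_g_per_kg_mean <- 0.75
  ind$protein_g_per_kg_sd <- 0
  ind$body_weight_kg <- 60
  ind$fat_pct_min <- 1
  ind$fat_pct_max <- 35
  e_weekly <- 7 * 2000
  if (kind == "single") {
    foods <- mkfood("grain", "staples", 100)  # 1 kcal per gram
    prices <- data.frame(food_id = "grain", cost_per_100g_edible = 0.5)
    cost <- e_weekly / 1 * 0.005  # 7E grams at cost per gram
    level <- "energy_only"
  } else if (kind == "tie") {
    foods <- rbind(mkfood("grain_a", "staples", 100),
                   mkfood("grain_b", "staples", 100))
    prices <- data.frame(food_id = c("grain_a", "grain_b"),
                         cost_per_100g_edible = c(0.5, 0.5))
    cost <- e_weekly / 1 * 0.005
    level <- "energy_only"
  } else {
    foods <- rbind(mkfood("starch", "staples", 360),
                   mkfood("pulse", "legumes", 340, protein = 24,
                          fat = 1.5))
    prices <- data.frame(food_id = c("pulse", "starch"),
                         cost_per_100g_edible = c(1.2, 0.4))
    protein_weekly <- 7 * 0.75 * 60
    pulse_g <- protein_weekly / 0.24
    starch_g <- (e_weekly - pulse_g * 3.4) / 3.6
    cost <- pulse_g * 0.012 + starch_g * 0.004
    level <- "macronutrients"
  }
  list(foods = foods, prices = prices, individual = ind, level = level,
       config = diet_config(), optimal_cost = cost)
}

#' Random small problem instance for solver verification
#'
#' Samples 1-3 archetype foods, a perturbed individual, a diet level and
#' random seasonal costs, deterministically from the seed.  Used to compare
#' the simplex route with the brute-force vertex-enumeration oracle over many
#' seeds; instances may be feasible or infeasible and both routes must agree.
#'
#' @param seed Integer seed.
#' @return List with `foods`, `prices`, `individual`, `level`, `habits`.
#' @export
random_small_instance <- function(seed) {
  local_seed(seed, {
    pool <- demo_foods()
    pool <- pool[pool$food_id != "salt", , drop = FALSE]  # zero-energy food
    n <- sample(1:3, 1)
    foods <- pool[sample(nrow(pool), n), , drop = FALSE]
    prices <- data.frame(food_id = foods$food_id,
                         cost_per_100g_edible = round(exp(stats::runif(
                           n, log(0.3), log(40))), 4))
    inds <- demo_individuals()
    ind <- inds[sample(which(inds$label != "infant_3m"), 1), , drop = FALSE]
    sc <- stats::runif(1, 0.8, 1.2)
    ind$energy_ear_kcal <- ind$energy_ear_kcal * sc
    ind$energy_sd_kcal <- ind$energy_sd_kcal * sc
    level <- sample(diet_levels(), 1)
    habits <- NULL
    if (level == "food_habits") {
      minf <- sample(0:3, n, replace = TRUE)
      habits <- data.frame(food_id = foods$food_id, min_per_week = minf,
                           max_per_week = minf + sample(4:21, n,
                                                        replace = TRUE))
    }
    list(foods = foods, prices = prices, individual = ind, level = level,
         habits = habits)
  })
}
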