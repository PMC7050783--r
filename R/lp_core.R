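# Assembly and solution of the weekly least-cost diet linear programme.
#
# One problem = one individual x one season x one diet level.  Variables are
# weekly edible grams per food (continuous); the objective is weekly cost.
# The LP is weekly because food-frequency constraints are weekly; daily
# figures are weekly / 7.  Generic simplex solves go through boot::simplex
# (with a pracma::linprog fallback); all problem assembly, diagnostics and
# the brute-force verification oracle live here.

#' Diet levels
#'
#' The four standard diets, in order of nested constraint sets: energy only;
#' plus protein and a fat band (macronutrients); plus 13 micronutrient minima
#' and 5 toxicity upper limits (nutritious); plus per-food weekly frequency
#' bounds from local dietary habits (food habits nutritious).
#'
#' @return Character vector of the four level names.
#' @export
diet_levels <- function() {
  c("energy_only", "macronutrients", "nutritious", "food_habits")
}

#' Solver and formulation configuration
#'
#' @param energy_percentile Percentile of the energy EAR distribution
#'   (default 50, the EAR itself).
#' @param protein_percentile Percentile of the per-kg protein requirement
#'   distribution (default 95).
#' @param micronutrient_percentile Optional percentile applied to all
#'   adjustable micronutrients; `NULL` (default) uses the stored RNI.
#' @param zinc_bioavailability Dietary zinc bioavailability: `"moderate"`
#'   (default), `"low"` or `"high"`.
#' @param iron_basis `"absorbed"` (default): each food's iron is multiplied
#'   by its absorption factor and compared with an absorbed-iron requirement;
#'   `"dietary"`: raw iron against a dietary requirement.  The iron toxicity
#'   upper limit is always applied to raw dietary iron.
#' @param fgmax Weekly servings ceiling per food group (default 105 = 5 foods
#'   x 3 meals x 7 days).
#' @param energy_tolerance Relative half-width of the band implementing the
#'   energy equality constraint.
#' @param constraint_tol Absolute feasibility tolerance on scaled constraint
#'   rows.
#' @param scheme A [portion_scheme()].
#' @return A `diet_config` list.
#' @export
diet_config <- function(energy_percentile = 50,
                        protein_percentile = 95,
                        micronutrient_percentile = NULL,
                        zinc_bioavailability = "moderate",
                        iron_basis = c("absorbed", "dietary"),
                        fgmax = 105,
                        energy_tolerance = 1e-6,
                        constraint_tol = 1e-6,
                        scheme = portion_scheme()) {
  structure(list(
    energy_percentile = energy_percentile,
    protein_percentile = protein_percentile,
    micronutrient_percentile = micronutrient_percentile,
    zinc_bioavailability = zinc_bioavailability,
    iron_basis = match.arg(iron_basis),
    fgmax = fgmax,
    energy_tolerance = energy_tolerance,
    constraint_tol = constraint_tol,
    scheme = scheme
  ), class = "diet_config")
}

#' @noRd
micronutrient_weekly_specs <- function(ind, config) {
  micros <- micro_keys()
  reg <- nutrient_registry()
  spec <- numeric(length(micros))
  names(spec) <- micros
  for (m in micros) {
    daily <-
      if (m == "zinc") {
        zinc_spec(ind, config$zinc_bioavailability)
      } else {
        ind_field(ind, paste0("rni_", m))
      }
    adjustable <- reg$percentile_adjustable[match(m, reg$key)]
    if (!is.null(config$micronutrient_percentile) && adjustable &&
        !is_infant(ind)) {
      sd <- ind_field(ind, paste0("rni_sd_", m))
      daily <- (daily - RNI_Z * sd) +
        z_of_percentile(config$micronutrient_percentile) * sd
    }
    spec[m] <- daily
  }
  7 * spec
}

#' Assemble the weekly diet problem for one individual
#'
#' Builds the cost vector and every constraint row for the requested diet
#' level: the energy equality (as a narrow band), the total food weight
#' ceiling and per-group servings ceilings at every level; the protein
#' minimum and fat band from the macronutrients level; the 13 micronutrient
#' minima and 5 upper limits from the nutritious level; and per-food weekly
#' bounds (portion x frequency) at the food-habits level only.
#'
#' @param foods Validated food table.
#' @param prices Data frame `food_id`, `cost_per_100g_edible` for one season.
#'   Foods without a price are excluded with a warning.
#' @param ind One individual (row of a validated individuals table).
#' @param level One of [diet_levels()].
#' @param habits Data frame `food_id`, `min_per_week`, `max_per_week`;
#'   required at the food-habits level, where every priced food must have an
#'   entry.  Setting both frequencies to 0 excludes a food.
#' @param config A [diet_config()].
#' @return A `diet_problem` object.
#' @export
diet_problem <- function(foods, prices, ind, level = "nutritious",
                         habits = NULL, config = diet_config()) {
  level <- match.arg(level, diet_levels())
  if (level == "food_habits" && is.null(habits))
    stop("dietary habit constraints are required for the food-habits diet")
  foods <- as.data.frame(unclass(foods), stringsAsFactors = FALSE)
  ind <- as.list(ind)

  unpriced <- setdiff(foods$food_id, prices$food_id)
  if (length(unpriced) > 0L) {
    warning("excluding food(s) with no seasonal price: ",
            paste(unpriced, collapse = ", "))
    foods <- foods[!foods$food_id %in% unpriced, , drop = FALSE]
  }
  if (nrow(foods) == 0L) stop("no priced foods available")
  foods <- foods[order(foods$food_id), , drop = FALSE]  # deterministic order
  n <- nrow(foods)
  cost_per_g <- prices$cost_per_100g_edible[
    match(foods$food_id, prices$food_id)] / 100
  if (any(is.na(cost_per_g)) || any(cost_per_g < 0))
    stop("invalid seasonal cost")

  # nutrient coefficients per edible gram
  reg <- nutrient_registry()
  nut_per_g <- t(as.matrix(foods[reg$food_column])) / 100
  rownames(nut_per_g) <- reg$key
  iron_absorbed_per_g <- nut_per_g["iron", ] * foods$iron_absorption_factor

  energy_daily <- energy_at_percentile(ind, config$energy_percentile)
  energy_weekly <- 7 * energy_daily
  tfw_weekly <- 7 * total_food_weight_limit(ind)

  portions <- unname(vapply(foods$food_group,
                            function(g) portion_size(ind, g, config$scheme),
                            numeric(1)))

  rows <- list()
  add_row <- function(coef, dir, rhs, kind, nutrient = NA_character_,
                      weekly_spec = NA_real_) {
    rows[[length(rows) + 1L]] <<- list(coef = coef, dir = dir, rhs = rhs,
                                       kind = kind, nutrient = nutrient,
                                       weekly_spec = weekly_spec)
  }

  e <- unname(nut_per_g["energy", ])
  tol <- config$energy_tolerance
  add_row(e, ">=", energy_weekly * (1 - tol), "energy_lo", "energy",
          energy_weekly)
  add_row(e, "<=", energy_weekly * (1 + tol), "energy_hi", "energy",
          energy_weekly)
  add_row(rep(1, n), "<=", tfw_weekly, "tfw", NA_character_, tfw_weekly)

  for (g in unique(foods$food_group)) {
    coef <- ifelse(foods$food_group == g, 1 / portions, 0)
    add_row(coef, "<=", config$fgmax, paste0("group:", g))
  }

  specs <- list(energy = energy_weekly)
  if (level %in% c("macronutrients", "nutritious", "food_habits")) {
    protein_daily <-
      if (is_infant(ind)) {
        bm <- foods[foods$food_group == "breast milk", , drop = FALSE]
        if (nrow(bm) == 0L)
          stop("breast-milk composition required for the infant protein rule")
        infant_protein_spec(ind, bm[1, ])
      } else {
        protein_spec(ind, config$protein_percentile)
      }
    protein_weekly <- 7 * protein_daily
    fat_daily <- fat_bounds_g(ind)
    add_row(unname(nut_per_g["protein", ]), ">=", protein_weekly,
            "protein", "protein", protein_weekly)
    add_row(unname(nut_per_g["fat", ]), ">=", 7 * fat_daily[["min"]],
            "fat_min", "fat", 7 * fat_daily[["min"]])
    add_row(unname(nut_per_g["fat", ]), "<=", 7 * fat_daily[["max"]],
            "fat_max", "fat", 7 * fat_daily[["max"]])
    specs$protein <- protein_weekly
    specs$fat_min <- 7 * fat_daily[["min"]]
    specs$fat_max <- 7 * fat_daily[["max"]]
  }

  if (level %in% c("nutritious", "food_habits")) {
    micro_weekly <- micronutrient_weekly_specs(ind, config)
    for (m in names(micro_weekly)) {
      coef <- if (m == "iron" && config$iron_basis == "absorbed")
        unname(iron_absorbed_per_g) else unname(nut_per_g[m, ])
      add_row(coef, ">=", micro_weekly[[m]], paste0("micro_lo:", m), m,
              micro_weekly[[m]])
    }
    for (m in upper_limit_keys()) {
      ul_weekly <- 7 * ind_field(ind, paste0("ul_", m))
      add_row(unname(nut_per_g[m, ]), "<=", ul_weekly, paste0("ul:", m), m,
              ul_weekly)
    }
    specs$micro <- micro_weekly
  }

  bounds_lo <- rep(0, n)
  bounds_hi <- rep(Inf, n)
  if (level == "food_habits") {
    idx <- match(foods$food_id, habits$food_id)
    if (any(is.na(idx)))
      stop("no habit frequencies for food(s): ",
           paste(foods$food_id[is.na(idx)], collapse = ", "))
    minf <- habits$min_per_week[idx]
    maxf <- habits$max_per_week[idx]
    if (any(minf < 0) || any(minf > maxf))
      stop("habit frequencies must satisfy 0 <= min <= max")
    bounds_lo <- portions * minf
    bounds_hi <- portions * maxf
    for (i in seq_len(n)) {
      unit <- as.numeric(seq_len(n) == i)
      if (bounds_lo[i] > 0)
        add_row(unit, ">=", bounds_lo[i], paste0("bound_lo:", foods$food_id[i]))
      add_row(unit, "<=", bounds_hi[i], paste0("bound_hi:", foods$food_id[i]))
    }
  }

  A <- do.call(rbind, lapply(rows, `[[`, "coef"))
  meta <- data.frame(
    kind = vapply(rows, `[[`, character(1), "kind"),
    dir = vapply(rows, `[[`, character(1), "dir"),
    rhs = vapply(rows, `[[`, numeric(1), "rhs"),
    nutrient = vapply(rows, `[[`, character(1), "nutrient"),
    weekly_spec = vapply(rows, `[[`, numeric(1), "weekly_spec"),
    stringsAsFactors = FALSE
  )
  rownames(A) <- meta$kind

  # coefficient matrix used for achievement reporting (absorbed iron in
  # absorbed mode so provision and requirement share a basis)
  ach_coef <- nut_per_g
  if (config$iron_basis == "absorbed") ach_coef["iron", ] <- iron_absorbed_per_g

  structure(list(
    foods = foods, n = n, cost_per_g = cost_per_g,
    A = A, meta = meta,
    nut_per_g = nut_per_g, ach_coef = ach_coef,
    portions = portions,
    bounds_lo = bounds_lo, bounds_hi = bounds_hi,
    specs = specs, level = level,
    individual = ind$label %||% "individual",
    tol = config$constraint_tol,
    config = config
  ), class = "diet_problem")
}

# ---- generic LP plumbing ---------------------------------------------------

#' @noRd
lp_run <- function(objective, A, dir, rhs, n_iter = 5000) {
  keep <- !(dir == ">=" & rhs <= 0 &
              apply(A, 1, function(r) all(r >= 0)))  # vacuous under x >= 0
  A <- A[keep, , drop = FALSE]
  dir <- dir[keep]
  rhs <- rhs[keep]
  scale <- pmax(apply(abs(A), 1, max), abs(rhs), 1e-12)
  A <- A / scale
  rhs <- rhs / scale
  le <- dir == "<="
  res <- tryCatch(
    boot::simplex(a = objective,
                  A1 = if (any(le)) A[le, , drop = FALSE],
                  b1 = if (any(le)) rhs[le],
                  A2 = if (any(!le)) A[!le, , drop = FALSE],
                  b2 = if (any(!le)) rhs[!le],
                  maxi = FALSE, n.iter = n_iter, eps = 1e-10),
    error = function(e) NULL)
  ok <- function(x) {
    slack_ok <- TRUE
    if (any(le))
      slack_ok <- all(A[le, , drop = FALSE] %*% x - rhs[le] <= 1e-7)
    if (slack_ok && any(!le))
      slack_ok <- all(A[!le, , drop = FALSE] %*% x - rhs[!le] >= -1e-7)
    slack_ok && all(x >= -1e-9)
  }
  if (!is.null(res) && res$solved == 1 && ok(res$soln))
    return(list(status = "optimal", x = pmax(res$soln, 0),
                value = sum(objective * res$soln)))
  if (!is.null(res) && res$solved == -1)
    return(list(status = "infeasible", x = NULL, value = NA_real_))
  # fallback route: pracma two-phase implementation.  linprog touches the
  # RNG stream, so pin it locally to keep solves bit-for-bit reproducible
  # regardless of caller state.
  Ale <- rbind(A[le, , drop = FALSE], -A[!le, , drop = FALSE])
  ble <- c(rhs[le], -rhs[!le])
  res2 <- local_seed(20231107, tryCatch(
    suppressWarnings(pracma::linprog(cc = objective, A = Ale, b = ble,
                                     maxiter = 200 + 20 * length(objective),
                                     maximize = FALSE)),
    error = function(e) NULL))
  if (!is.null(res2) && !is.null(res2$x) &&
      length(res2$x) == length(objective) && ok(res2$x))
    return(list(status = "optimal", x = pmax(res2$x, 0),
                value = sum(objective * res2$x)))
  list(status = "infeasible", x = NULL, value = NA_real_)
}

# ---- solving ---------------------------------------------------------------

#' @noRd
finish_solution <- function(problem, x, status, shortfall = NULL,
                            warnings = character(0)) {
  m <- problem$meta
  provided <- drop(problem$ach_coef %*% x)
  specs <- problem$specs
  ach <- c(energy = unname(100 * provided["energy"] / specs$energy))
  if (!is.null(specs$protein)) {
    ach["protein"] <- 100 * provided["protein"] / specs$protein
    ach["fat"] <- if (specs$fat_min > 0)
      100 * provided["fat"] / specs$fat_min else NA_real_
  }
  if (!is.null(specs$micro)) {
    for (k in names(specs$micro))
      ach[k] <- if (specs$micro[[k]] > 0)
        100 * provided[k] / specs$micro[[k]] else NA_real_
  }
  lhs <- drop(problem$A %*% x)
  scale <- pmax(abs(m$rhs), 1)
  binding <- abs(lhs - m$rhs) / scale <= 1e-6
  ul_rows <- grepl("^ul:", m$kind)
  binding_ul <- m$nutrient[ul_rows & binding]
  tfw_binding <- any(m$kind == "tfw" & binding)
  if ((tfw_binding || length(binding_ul) > 0) && status == "relaxed")
    warnings <- c(warnings,
                  paste("This diet cannot be calculated, because an upper",
                        "limit was reached, this will be either food weight",
                        "or one of the nutrients"))
  grams <- stats::setNames(x, problem$foods$food_id)
  servings <- tapply(x / problem$portions, problem$foods$food_group, sum)
  structure(list(
    status = status,
    level = problem$level,
    individual = problem$individual,
    weekly_grams = grams,
    weekly_cost = sum(problem$cost_per_g * x),
    provided_weekly = provided,
    achievement_pct = ach,
    binding_upper_limits = binding_ul,
    tfw_binding = tfw_binding,
    servings_used = as.list(servings),
    shortfall = shortfall,
    warnings = warnings
  ), class = "diet_solution")
}

#' Solve a diet problem
#'
#' Minimises weekly cost subject to all assembled constraints.  Infeasibility
#' is reported through the solution status, never as an error; the result is
#' deterministic given the (sorted) food ordering and solver settings.
#'
#' @param problem A [diet_problem()].
#' @return A `diet_solution` with status `"optimal"` or `"infeasible"`.
#' @export
solve_diet <- function(problem) {
  res <- lp_run(problem$cost_per_g, problem$A, problem$meta$dir,
                problem$meta$rhs)
  if (res$status != "optimal")
    return(structure(list(status = "infeasible", level = problem$level,
                          individual = problem$individual,
                          weekly_grams = NULL, weekly_cost = NA_real_,
                          achievement_pct = NULL,
                          binding_upper_limits = character(0),
                          shortfall = NULL, warnings = character(0)),
                     class = "diet_solution"))
  finish_solution(problem, res$x, "optimal")
}

#' Diagnose an infeasible diet by minimising nutrient shortfalls
#'
#' Two-stage goal programme.  Stage 1 keeps every upper limit, the total
#' food weight ceiling, group ceilings and per-food bounds hard, allows each
#' nutrient lower bound (and the lower side of the energy band) to fall
#' short by a proportional slack in \[0, 1\], and minimises the summed
#' shortfall.  Stage 2 minimises cost at the stage-1 shortfall optimum.
#' Nutrients that fall short then report achievement below 100%.
#'
#' @param problem A [diet_problem()].
#' @return A `diet_solution` with status `"relaxed"` (or `"optimal"` if the
#'   problem was feasible after all, or `"infeasible"` if even the relaxation
#'   has contradictory hard constraints).
#' @export
relaxed_solve <- function(problem) {
  base <- solve_diet(problem)
  if (base$status == "optimal") return(base)
  m <- problem$meta
  relaxable <- m$dir == ">=" & !grepl("^bound_lo:", m$kind)
  K <- sum(relaxable)
  n <- problem$n
  widen <- function(A) cbind(A, matrix(0, nrow(A), K))
  A1 <- widen(problem$A)
  slack_col <- n + seq_len(K)
  A1[cbind(which(relaxable), slack_col)] <- m$rhs[relaxable]
  # s_k <= 1
  cap <- matrix(0, K, n + K)
  cap[cbind(seq_len(K), slack_col)] <- 1
  A_all <- rbind(A1, cap)
  dir_all <- c(m$dir, rep("<=", K))
  rhs_all <- c(m$rhs, rep(1, K))
  obj1 <- c(rep(0, n), rep(1, K))
  st1 <- lp_run(obj1, A_all, dir_all, rhs_all)
  if (st1$status != "optimal")
    return(structure(list(
      status = "infeasible", level = problem$level,
      individual = problem$individual, weekly_grams = NULL,
      weekly_cost = NA_real_, achievement_pct = NULL,
      binding_upper_limits = character(0), shortfall = NULL,
      warnings = paste("contradictory hard constraints:",
                       paste(m$kind[!relaxable], collapse = ", "))),
      class = "diet_solution"))
  s_total <- sum(st1$x[slack_col])
  A2 <- rbind(A_all, obj1)
  dir2 <- c(dir_all, "<=")
  rhs2 <- c(rhs_all, s_total + 1e-9 * max(1, s_total))
  st2 <- lp_run(c(problem$cost_per_g, rep(0, K)), A2, dir2, rhs2)
  if (st2$status != "optimal") st2 <- st1  # cost polish failed; keep stage 1
  x <- st2$x[seq_len(n)]
  s <- st2$x[slack_col]
  short <- stats::setNames(s * m$weekly_spec[relaxable],
                           ifelse(is.na(m$nutrient[relaxable]),
                                  m$kind[relaxable], m$nutrient[relaxable]))
  short <- short[s > 1e-7]
  finish_solution(problem, x, "relaxed", shortfall = short)
}

#' Nutrient achievement of a solution
#'
#' Percentage of each weekly specification provided by the solution:
#' `100 * provided / (7 x daily spec)`.  Exactly 100 marks the binding
#' nutrient; values above 100 are allowed for nutrients without upper
#' limits.  A zero specification is reported as `NA` (not applicable).
#'
#' @param solution A `diet_solution` with amounts.
#' @return Named numeric vector of percentages.
#' @export
achievement <- function(solution) {
  if (is.null(solution$achievement_pct))
    stop("solution has no amounts (status ", solution$status, ")")
  solution$achievement_pct
}

#' Brute-force verification oracle for small problems
#'
#' Independent optimum by enumeration of all basic feasible vertices of the
#' constraint polytope (every intersection of n constraint hyperplanes,
#' including the non-negativity bounds).  Refuses more than 3 foods.  The
#' feasible region is bounded (total food weight plus non-negativity), so a
#' non-empty region has a feasible vertex and enumeration is exact.
#'
#' @param problem A [diet_problem()] with at most 3 foods.
#' @param tol Feasibility tolerance on scaled rows.
#' @return List with `status`, `weekly_grams`, `weekly_cost`.
#' @export
brute_force_diet <- function(problem, tol = 1e-7) {
  n <- problem$n
  if (n > 3L) stop("brute-force oracle is limited to 3 foods")
  A <- rbind(problem$A, diag(n))
  dir <- c(problem$meta$dir, rep(">=", n))
  rhs <- c(problem$meta$rhs, rep(0, n))
  scale <- pmax(apply(abs(A), 1, max), abs(rhs), 1e-12)
  m <- nrow(A)
  feasible <- function(x) {
    lhs <- drop(A %*% x)
    dev <- (lhs - rhs) / scale
    all(dev[dir == "<="] <= tol) && all(dev[dir == ">="] >= -tol)
  }
  best_cost <- Inf
  best_x <- NULL
  for (idx in utils::combn(m, n, simplify = FALSE)) {
    B <- A[idx, , drop = FALSE]
    if (abs(det(B)) < 1e-12) next
    x <- tryCatch(solve(B, rhs[idx]), error = function(e) NULL)
    if (is.null(x) || !feasible(x)) next
    cost <- sum(problem$cost_per_g * x)
    if (cost < best_cost - 1e-15) {
      best_cost <- cost
      best_x <- x
    }
  }
  if (is.null(best_x))
    return(list(status = "infeasible", weekly_grams = NULL,
                weekly_cost = NA_real_))
  list(status = "optimal",
       weekly_grams = stats::setNames(pmax(best_x, 0),
                                      problem$foods$food_id),
       weekly_cost = best_cost)
}

#' Check a gram vector against every constraint of a problem
#'
#' @param problem A [diet_problem()].
#' @param x Weekly grams per food, in problem food order.
#' @param tol Tolerance on scaled rows.
#' @return Logical: `TRUE` if every row is satisfied; violated row kinds are
#'   attached as attribute `"violated"`.
#' @export
satisfies_constraints <- function(problem, x, tol = 1e-6) {
  lhs <- drop(problem$A %*% x)
  rhs <- problem$meta$rhs
  scale <- pmax(apply(abs(problem$A), 1, max) * max(abs(x), 1), abs(rhs), 1)
  dev <- (lhs - rhs) / scale
  bad <- (problem$meta$dir == "<=" & dev > tol) |
    (problem$meta$dir == ">=" & dev < -tol)
  bad <- bad | FALSE
  out <- !any(bad) && all(x >= -tol * max(abs(x), 1))
  attr(out, "violated") <- problem$meta$kind[bad]
  out
}

# ---- methods ---------------------------------------------------------------

#' @export
print.diet_problem <- function(x, ...) {
  cat("Weekly least-cost diet problem\n")
  cat("  individual:", x$individual, "  level:", x$level, "\n")
  cat("  foods:", x$n, "  constraint rows:", nrow(x$meta), "\n")
  invisible(x)
}

#' @export
print.diet_solution <- function(x, ...) {
  cat("Diet solution (", x$level, ", ", x$individual, "): ",
      x$status, "\n", sep = "")
  if (!is.null(x$weekly_grams)) {
    cat("  weekly cost:", format(round(x$weekly_cost, 2)), "\n")
    sel <- x$weekly_grams[x$weekly_grams > 0.05]
    cat("  foods selected:", length(sel), "\n")
  }
  if (!is.null(x$shortfall) && length(x$shortfall) > 0)
    cat("  short nutrients:", paste(names(x$shortfall), collapse = ", "),
        "\n")
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' @export
summary.diet_solution <- function(object, ...) {
  print(object)
  if (!is.null(object$achievement_pct)) {
    cat("  achievement (% of specification):\n")
    a <- round(object$achievement_pct, 1)
    for (k in names(a))
      cat(sprintf("    %-18s %s\n", gsub("_", " ", k),
                  ifelse(is.na(a[k]), "n/a", a[k])))
  }
  invisible(object)
}

#' @export
coef.diet_solution <- function(object, ...) object$weekly_grams
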