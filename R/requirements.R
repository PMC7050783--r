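# Energy, protein, fat and micronutrient specifications per individual,
# portion-size scaling from a reference child, and household assembly.
#
# Energy is specified as the estimated average requirement (EAR, probability
# 0.5 of meeting an individual's need); protein defaults to the 95th
# percentile of the per-kg requirement distribution; micronutrients default
# to the RNI, defined as 2 SD above the average requirement (probability
# 0.97725).  Dispersions are modelled as normal with per-nutrient SDs
# supplied in the individuals table.

BREAST_MILK_ENERGY_KCAL_PER_ML <- 0.67
FAT_ENERGY_KCAL_PER_G <- 9
RNI_Z <- 2  # the RNI sits 2 SD above the mean requirement

#' @noRd
z_of_percentile <- function(p) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 1 || p > 99)
    stop("percentile must lie between 1 and 99")
  stats::qnorm(p / 100)
}

#' @noRd
ind_field <- function(ind, field) {
  v <- ind[[field]]
  if (is.null(v) || length(v) != 1L || is.na(v))
    stop("individual '", ind$label %||% "?", "' lacks field '", field, "'")
  v
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
is_infant <- function(ind) {
  age <- ind[["age_months"]]
  !is.null(age) && !is.na(age) && age <= 12
}

#' Energy specification at a percentile of the EAR distribution
#'
#' @param ind One individual: a one-row data frame or named list from the
#'   individuals table.
#' @param p Percentile in \[1, 99\]; 50 returns the EAR itself.
#' @return kcal/day.
#' @export
energy_at_percentile <- function(ind, p = 50) {
  z <- z_of_percentile(p)
  ind_field(ind, "energy_ear_kcal") + z * ind_field(ind, "energy_sd_kcal")
}

#' Protein specification from the per-kg requirement distribution
#'
#' The daily specification is the chosen percentile of the requirement per kg
#' body weight multiplied by body weight.  Applies to individuals older than
#' 12 months; infant protein comes from [infant_protein_spec()].
#'
#' @inheritParams energy_at_percentile
#' @param p Percentile in \[1, 99\]; default 95.
#' @return g/day.
#' @export
protein_spec <- function(ind, p = 95) {
  if (is_infant(ind))
    stop("percentile-based protein specification applies only to ",
         "individuals aged >12 months")
  z <- z_of_percentile(p)
  per_kg <- ind_field(ind, "protein_g_per_kg_mean") +
    z * ind_field(ind, "protein_g_per_kg_sd")
  per_kg * ind_field(ind, "body_weight_kg")
}

#' Infant protein specification from breast-milk composition
#'
#' For children aged 1-6 months the protein specification is the protein
#' contained in the volume of breast milk needed to meet the energy EAR at an
#' energy density of 0.67 kcal/ml.
#'
#' @inheritParams energy_at_percentile
#' @param breast_milk A food-table row for breast milk (protein per 100 g
#'   edible and specific gravity), or `NULL` if `protein_per_ml` is given.
#' @param protein_per_ml Protein concentration of breast milk in g/ml;
#'   derived from `breast_milk` when omitted.
#' @return g/day.
#' @export
infant_protein_spec <- function(ind, breast_milk = NULL,
                                protein_per_ml = NULL) {
  if (is.null(protein_per_ml)) {
    if (is.null(breast_milk))
      stop("breast-milk composition required for the infant protein rule")
    sg <- breast_milk[["specific_gravity"]]
    if (is.null(sg) || is.na(sg))
      stop("specific gravity required to express breast milk per ml")
    protein_per_ml <- breast_milk[["protein_g"]] / 100 * sg
  }
  volume_ml <- ind_field(ind, "energy_ear_kcal") /
    BREAST_MILK_ENERGY_KCAL_PER_ML
  volume_ml * protein_per_ml
}

#' Fat bounds in grams per day
#'
#' The minimum and maximum percentage of dietary energy from fat (defaults 20
#' and 35 for adults) converted to grams at 9 kcal/g.
#'
#' @inheritParams energy_at_percentile
#' @param pct_min,pct_max Optional overrides of the individual's stored
#'   percentages, each in \[1, 99\].
#' @return Named numeric `c(min = , max = )` in g/day.
#' @export
fat_bounds_g <- function(ind, pct_min = NULL, pct_max = NULL) {
  lo <- pct_min %||% ind_field(ind, "fat_pct_min")
  hi <- pct_max %||% ind_field(ind, "fat_pct_max")
  for (p in c(lo, hi))
    if (p < 1 || p > 99) stop("fat percentage must lie between 1 and 99")
  if (lo > hi) stop("minimum fat percentage exceeds maximum")
  e <- ind_field(ind, "energy_ear_kcal")
  c(min = lo * e / 100 / FAT_ENERGY_KCAL_PER_G,
    max = hi * e / 100 / FAT_ENERGY_KCAL_PER_G)
}

#' Micronutrient specification at a percentile of the RNI distribution
#'
#' The RNI is defined as 2 SD above the mean requirement, so the mean is
#' `rni - 2*sd` and the specification at percentile `p` is `mean + z(p)*sd`.
#' At p = 97.725 this reproduces the stored RNI.  Vitamin A is a recommended
#' safe intake and is never adjusted; no adjustment factors exist for
#' pantothenic acid or magnesium; individuals aged 12 months or less are not
#' adjusted.
#'
#' @inheritParams energy_at_percentile
#' @param nutrient Canonical micronutrient key (see [nutrient_registry()]).
#' @param p Percentile in \[1, 99\].
#' @return Amount/day in the nutrient's unit.
#' @export
micronutrient_at_percentile <- function(ind, nutrient, p) {
  reg <- nutrient_registry()
  row <- match(nutrient, reg$key)
  if (is.na(row) || reg$class[row] != "micro")
    stop("unknown micronutrient: ", nutrient)
  if (nutrient == "vitamin_a")
    stop("vitamin A is a recommended safe intake and cannot be ",
         "percentile-adjusted")
  if (!reg$percentile_adjustable[row])
    stop("no adjustment factors published for ", gsub("_", " ", nutrient))
  if (is_infant(ind))
    stop("micronutrient percentile adjustment applies only to individuals ",
         "aged >12 months")
  z <- z_of_percentile(p)
  rni <- ind_field(ind, paste0("rni_", nutrient))
  sd <- ind_field(ind, paste0("rni_sd_", nutrient))
  (rni - RNI_Z * sd) + z * sd
}

#' Zinc specification by dietary bioavailability
#'
#' @inheritParams energy_at_percentile
#' @param level `"low"`, `"moderate"` (default) or `"high"` bioavailability;
#'   a low-bioavailability diet needs more zinc.
#' @return mg/day.
#' @export
zinc_spec <- function(ind, level = c("moderate", "low", "high")) {
  level <- match.arg(level)
  ind_field(ind, paste0("zinc_rni_", level, "_mg"))
}

#' Portion-size scaling factor relative to the reference child
#'
#' Portions for any individual scale from the 1-3 year reference child by the
#' ratio of the individual's mean + 2 SD energy specification to the
#' reference child's mean energy requirement.
#'
#' @inheritParams energy_at_percentile
#' @param reference_energy_kcal Mean energy requirement of the 1-3 y
#'   reference child, kcal/day.
#' @return Dimensionless factor.
#' @export
portion_scaling_factor <- function(ind, reference_energy_kcal = 1000) {
  if (reference_energy_kcal <= 0)
    stop("reference child energy must be positive")
  (ind_field(ind, "energy_ear_kcal") +
     2 * ind_field(ind, "energy_sd_kcal")) / reference_energy_kcal
}

#' Portion scheme: grams per meal by food group
#'
#' Standard portions per meal for the reference child aged 1-3 years, by food
#' group, plus fixed (unscaled) portions for the exception groups: breast
#' milk, milk powder, supplements, infant foods, sugars and confectionery,
#' and condiments.  All defaults are editable data, not code constants.
#'
#' @param child_portions_g Named numeric vector: grams per meal per food
#'   group for the reference child.
#' @param fixed_portions_g Named numeric vector of fixed portions for the
#'   scaling-exempt groups.
#' @param reference_energy_kcal Mean energy requirement of the reference
#'   child.
#' @return A `portion_scheme` list.
#' @export
portion_scheme <- function(
    child_portions_g = c("staples" = 120, "legumes" = 50, "vegetables" = 60,
                         "fruits" = 80, "animal products" = 40, "fish" = 40,
                         "oils and fats" = 12, "milk and dairy" = 180,
                         "eggs" = 50),
    fixed_portions_g = c("breast milk" = 120, "milk powder" = 25,
                         "supplements" = 5, "infant foods" = 100,
                         "sugars and confectionery" = 10, "condiments" = 2),
    reference_energy_kcal = 1000) {
  if (any(child_portions_g <= 0) || any(fixed_portions_g <= 0))
    stop("all portions must be positive")
  structure(list(child_portions_g = child_portions_g,
                 fixed_portions_g = fixed_portions_g,
                 reference_energy_kcal = reference_energy_kcal),
            class = "portion_scheme")
}

#' Portion size of a food for an individual
#'
#' The reference-child portion for the food's group multiplied by the
#' individual's scaling factor; exception groups use their fixed portion
#' unscaled.
#'
#' @inheritParams energy_at_percentile
#' @param food_group Food-group name.
#' @param scheme A [portion_scheme()].
#' @return Grams per meal.
#' @export
portion_size <- function(ind, food_group, scheme = portion_scheme()) {
  if (food_group %in% names(scheme$fixed_portions_g))
    return(unname(scheme$fixed_portions_g[food_group]))
  if (!food_group %in% names(scheme$child_portions_g))
    stop("no portion configured for food group '", food_group, "'")
  unname(scheme$child_portions_g[food_group]) *
    portion_scaling_factor(ind, scheme$reference_energy_kcal)
}

#' Daily total food weight limit
#'
#' An upper limit on the grams of all food per day, standing in for stomach
#' capacity: the mean + 2 SD energy specification divided by an assumed low
#' dietary energy density of 1 kcal/g.  Not user-adjustable.
#'
#' @inheritParams energy_at_percentile
#' @return Grams per day.
#' @export
total_food_weight_limit <- function(ind) {
  ind_field(ind, "energy_ear_kcal") + 2 * ind_field(ind, "energy_sd_kcal")
}

#' Validate a season calendar
#'
#' One to six seasons whose day counts must sum to exactly 365.
#'
#' @param calendar Data frame with columns `name` and `days` (positive
#'   integers).
#' @return The calendar, invisibly, if valid.
#' @export
validate_calendar <- function(calendar) {
  if (!all(c("name", "days") %in% names(calendar)))
    stop("calendar needs columns 'name' and 'days'")
  n <- nrow(calendar)
  if (n < 1L || n > 6L) stop("between 1 and 6 seasons are allowed")
  if (any(calendar$days <= 0) || any(calendar$days != round(calendar$days)))
    stop("season lengths must be positive whole days")
  total <- sum(calendar$days)
  if (total != 365L)
    stop("season lengths sum to ", total, ", not 365 (",
         ifelse(total < 365, paste0("deficit ", 365 - total),
                paste0("excess ", total - 365)), " days)")
  invisible(calendar)
}

#' Validate an individuals table
#'
#' @param individuals Data frame in the individuals schema (see the package
#'   vignette): label, age_months, sex, is_lactating, body_weight_kg, energy
#'   EAR and SD, protein per-kg mean and SD, fat percentage band, 13 RNI
#'   columns, 10 RNI SD columns, 5 upper-limit columns and the 3 zinc
#'   bioavailability columns.
#' @param iron_basis `"absorbed"` or `"dietary"`; the iron upper limit is
#'   only comparable with the iron RNI on a dietary basis.
#' @return The table, invisibly, if valid.
#' @export
validate_individuals <- function(individuals, iron_basis = "absorbed") {
  reg <- nutrient_registry()
  micros <- micro_keys()
  sd_micros <- reg$key[reg$percentile_adjustable]
  required <- c("label", "age_months", "energy_ear_kcal", "energy_sd_kcal",
                "protein_g_per_kg_mean", "protein_g_per_kg_sd",
                "fat_pct_min", "fat_pct_max",
                paste0("rni_", micros), paste0("rni_sd_", sd_micros),
                paste0("ul_", upper_limit_keys()),
                paste0("zinc_rni_", c("low", "moderate", "high"), "_mg"))
  missing <- setdiff(required, names(individuals))
  if (length(missing) > 0L)
    stop("individuals table is missing columns: ",
         paste(missing, collapse = ", "))
  if (anyDuplicated(individuals$label))
    stop("duplicate individual labels")
  if (any(individuals$energy_ear_kcal <= 0))
    stop("energy EAR must be positive")
  for (m in micros)
    if (any(individuals[[paste0("rni_", m)]] < 0))
      stop("negative RNI for ", m)
  if (any(individuals$fat_pct_min > individuals$fat_pct_max))
    stop("fat_pct_min exceeds fat_pct_max")
  comparable <- setdiff(upper_limit_keys(), "vitamin_a")
  if (iron_basis != "dietary") comparable <- setdiff(comparable, "iron")
  for (m in comparable)
    if (any(individuals[[paste0("ul_", m)]] <
            individuals[[paste0("rni_", m)]]))
      stop("upper limit below RNI for ", m)
  if (any(individuals$ul_vitamin_a < individuals$rni_vitamin_a))
    stop("upper limit below safe intake for vitamin_a")
  bad_zinc <- individuals$zinc_rni_low_mg < individuals$zinc_rni_moderate_mg |
    individuals$zinc_rni_moderate_mg < individuals$zinc_rni_high_mg
  if (any(bad_zinc))
    stop("zinc RNIs must satisfy low >= moderate >= high bioavailability")
  invisible(individuals)
}

#' Assemble and check a standard family
#'
#' Standard families align with the Household Economy Approach: the mean
#' daily energy EAR per member must be within a tolerance (default 2%) of
#' 2,100 kcal/person, and the family must contain a child aged 12-23 months,
#' a lactating woman and an adult man.
#'
#' @param members Data frame of individuals (rows from a validated
#'   individuals table) with columns `age_months`, `sex`, `is_lactating`.
#' @param name Family name.
#' @param per_person_target_kcal Alignment target, kcal/person/day.
#' @param tolerance Relative tolerance on the mean member EAR.
#' @return A `standard_family` list with elements `name`, `members`,
#'   `mean_ear_kcal`.
#' @export
standard_family <- function(members, name = "standard family",
                            per_person_target_kcal = 2100,
                            tolerance = 0.02) {
  if (nrow(members) == 0L) stop("a family must have at least one member")
  mean_ear <- mean(members$energy_ear_kcal)
  if (abs(mean_ear - per_person_target_kcal) >
      tolerance * per_person_target_kcal)
    stop("family mean energy EAR (", round(mean_ear, 1),
         " kcal) is not within ", tolerance * 100, "% of ",
         per_person_target_kcal, " kcal/person")
  has_young_child <- any(members$age_months >= 12 & members$age_months <= 23)
  has_lactating <- any(isTRUE(members$is_lactating) | members$is_lactating)
  has_adult_man <- any(members$age_months >= 18 * 12 & members$sex == "m")
  if (!has_young_child || !has_lactating || !has_adult_man)
    stop("a standard family must include a child aged 12-23 months, ",
         "a lactating woman and an adult man")
  structure(list(name = name, members = members, mean_ear_kcal = mean_ear),
            class = "standard_family")
}

#' Read the individuals, seasons and households files
#'
#' @param path File path.
#' @return `read_individuals()` a validated individuals table;
#'   `read_seasons()` a validated calendar; `read_households()` a named list
#'   of character vectors of member labels.
#' @export
read_individuals <- function(path) {
  ind <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_individuals(ind)
  ind
}

#' @rdname read_individuals
#' @export
read_seasons <- function(path) {
  cal <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_calendar(cal)
  cal
}

#' @rdname read_individuals
#' @export
read_households <- function(path) {
  hh <- yaml::read_yaml(path)
  if (length(hh) == 0L) stop("no households defined")
  lapply(hh, function(m) as.character(unlist(m)))
}
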