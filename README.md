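# lcdiet

Least-cost diet linear programming for public-health nutrition and food
security assessment.

In food-insecure settings the usual obstacle to a nutritious diet is not
knowledge but money. `lcdiet` estimates the lowest possible cost of a diet
that meets the energy, protein, fat and micronutrient specifications of
individuals and households using foods priced in local markets, and then
asks whether the poorest wealth groups could afford it.

## The model

For each individual, season and diet level the package solves a weekly
linear programme over the edible grams `X_i ≥ 0` of each priced food:

```
min  Σ_i c_i X_i                                  (weekly cost)
s.t. Σ_i e_i X_i  = 7·E                           (energy equality, narrow band)
     Σ_i n_ik X_i ≥ 7·dnut_k   for each required nutrient k
     Σ_i n_ik X_i ≤ 7·unut_k   for vitamin A, vitamin C, niacin, calcium, iron
     a_i·fmin_i ≤ X_i ≤ a_i·fmax_i                (food-habits level only)
     Σ_{i∈s} X_i / a_i ≤ 105   per food group s   (servings ceiling)
     Σ_i X_i ≤ 7·TFW                              (total food weight)
```

where `c_i` is cost per edible gram (from a market price survey averaged to
cost per 100 g edible portion), `a_i` the individual's portion size (scaled
from a 1–3-year reference child by `(mean + 2 SD energy)/E_child`), and
`TFW = (EAR + 2 SD)/1 kcal g⁻¹` grams per day. Four nested diet levels are
costed: energy-only, macronutrients, nutritious (13 micronutrients with 5
toxicity upper limits), and food-habits nutritious (plus weekly frequency
bounds elicited from local women). Specifications are percentile-based:
energy at the EAR (50th), protein at the 95th percentile of per-kg
requirements, micronutrients at the RNI (= mean + 2 SD, the 97.725th
percentile), with iron on an absorbed basis and zinc by dietary
bioavailability. Infeasible diets are diagnosed with a two-stage shortfall
relaxation that reports achievement below 100% for the unreachable
nutrients. Costs aggregate over household members, a 1–6-season calendar
summing to 365 days, and the year; affordability is expressed against
wealth-group income and essential non-food expenditure.

See the vignette `vignettes/least-cost-diets.Rmd` for the full method,
parameter meanings and design choices.

## Worked example

The synthetic scenario generator builds a complete small economy — eleven
archetype foods in three markets over three seasons, a five-member standard
family averaging exactly 2,100 kcal/person/day, habit frequencies and four
wealth groups — reproducibly from a seed:

```r
library(lcdiet)
scenario   <- generate_scenario(seed = 42)
assessment <- run_assessment(scenario)
assessment
#> Diet assessment 'default': 1 household(s), 3 season(s), levels: energy_only, macronutrients, nutritious, food_habits
#>  household          level annual_cost all_optimal
#>  household    energy_only    45482.99        TRUE
#>  household macronutrients    50022.39        TRUE
#>  household     nutritious   106736.74        TRUE
#>  household    food_habits   108234.28        TRUE
```

Annual household cost rises from 45,483 currency units for bare energy to
108,234 when all nutrient specifications and local food habits must be
respected — the cost of a realistic nutritious diet here is 2.4 times the
cost of mere calories. Solutions carry per-nutrient achievement, with
binding nutrients at exactly 100%:

```r
summary(assessment$solutions$household$lean$nutritious$adult_man)
#> Diet solution (nutritious, adult_man): optimal
#>   weekly cost: 556.45
#>   foods selected: 5
#>   achievement (% of specification):
#>     energy             100
#>     protein            186.3
#>     fat                100
#>     vitamin a          100
#>     ...
#>     calcium            100
#>     magnesium          313.6
```

Energy, fat, vitamin A and calcium bind at 100% — calcium and vitamin A are
what the solver is paying for. Affordability against wealth groups:

```r
subset(affordability_table(assessment),
       level == "nutritious" & wealth_group %in% c("very poor", "better-off"))
#>  household      level wealth_group annual_cost pct_income pct_income_cumulative income_gap
#>  household nutritious    very poor    106736.7     355.79                395.79   88736.74
#>  household nutritious   better-off    106736.7      66.71                 94.84       0.00
```

The nutritious diet would take 3.6 times the very poor group's annual
income (an income gap of 88,737 after non-food expenditure), while the
better-off group could just cover it. A command-line wrapper over the same
functions is in `inst/cli/lcdiet.R`
(`fixtures` / `validate` / `solve` / `report`).

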