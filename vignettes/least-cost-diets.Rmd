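---
title: "Modelling the least-cost diet: method, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the least-cost diet: method, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcdiet)
```

## The problem

In many food-insecure settings the binding constraint on a nutritious diet
is economic, not informational: the foods needed to meet energy and nutrient
recommendations are on the market, but the poorest households cannot afford
them. `lcdiet` quantifies that constraint. Given locally priced foods, it
finds the cheapest weekly combination of foods that satisfies a set of
nutritional specifications for an individual, repeats the exercise across
household members, seasons and four increasingly realistic diet definitions,
and compares the resulting annual cost with wealth-group income.

## The optimisation model

For one individual in one season the decision variables are the weekly
edible grams $X_i \ge 0$ of each priced food $i$. With $c_i$ the cost per
edible gram, the solver minimises

$$\min \sum_i c_i X_i$$

subject to, depending on the diet level:

* **Energy equality** (all levels): $\sum_i e_i X_i = 7\,E$, with $e_i$ the
  energy density (kcal/g) and $E$ the daily energy specification. A strict
  equality is awkward numerically, so it is implemented as a pair of
  inequalities with a relative half-width of $10^{-6}$; the diet must not
  under- or over-shoot energy.
* **Total food weight** (all levels): $\sum_i X_i \le 7\,\mathrm{TFW}$ where
  $\mathrm{TFW} = (E_{\mathrm{EAR}} + 2\,\mathrm{SD})/1\ \mathrm{kcal\,g^{-1}}$
  grams per day, a stand-in for stomach capacity assuming a low dietary
  energy density. It is deliberately not user-adjustable.
* **Food-group servings** (all levels): for each food group $s$,
  $\sum_{i \in s} X_i / a_i \le 105$, where $a_i$ is the individual's
  portion size for that food and 105 = 5 foods × 3 meals × 7 days.
  Servings are continuous ($X_i/a_i$), not integers: the model is a pure
  LP, not a mixed-integer programme.
* **Protein and fat** (macronutrients level and above): protein
  $\ge$ 7 × the daily specification; fat within a band derived from minimum
  and maximum percentages of energy converted at 9 kcal/g.
* **Micronutrients** (nutritious level and above): thirteen lower bounds
  (vitamins A, C, B1, B2, niacin, B6, folic acid, B12, pantothenic acid,
  calcium, iron, magnesium, zinc) and five toxicity upper limits
  (vitamin A, vitamin C, niacin, calcium, iron) that may never be exceeded.
* **Dietary habits** (food-habits level only): per-food bounds
  $a_i\,f^{\min}_i \le X_i \le a_i\,f^{\max}_i$ from minimum and maximum
  weekly consumption frequencies. Setting both to zero excludes a food.

The LP is weekly because the frequency data are weekly; daily reports divide
by 7. The four levels are nested, so optimal cost is non-decreasing from
energy-only to food-habits whenever all levels are feasible — a property the
test-suite asserts rather than assumes.

Per-food portion ceilings bind only at the food-habits level. The nutritious
diet is limited only by total weight and the group ceiling: the method's own
description of its outputs states the nutritious diet may include any
combination of foods in amounts limited by total weight, not portion size,
and we follow that more specific statement over the generic constraint list.

## Requirement modelling

Specifications are percentile-based around published reference values,
with normal dispersion:

* **Energy** defaults to the estimated average requirement (EAR), the 50th
  percentile: half of a demographic group needs more, half less. Users may
  move any specification between the 1st and 99th percentile;
  $\mathrm{spec}(p) = \mu + z(p)\,\sigma$.
* **Protein** defaults to the 95th percentile of the per-kg requirement
  distribution times body weight. Children aged 1–6 months instead get the
  protein contained in the volume of breast milk that meets their energy
  EAR at 0.67 kcal/ml.
* **Micronutrients** default to the recommended nutrient intake (RNI),
  defined as 2 SD above the mean requirement, i.e. the 97.725th percentile.
  Percentile adjustment therefore recentres on $\mathrm{RNI} - 2\sigma$.
  Three exceptions refuse adjustment rather than silently ignoring it:
  vitamin A (a recommended safe intake, not a distributional quantity), and
  pantothenic acid and magnesium (no published adjustment factors). No
  adjustment is offered below 12 months of age.
* **Zinc** has three alternative RNIs by dietary bioavailability (low,
  moderate, high); moderate is the default. **Iron** is handled on an
  absorbed basis by default: each food's iron coefficient is multiplied by
  its absorption factor and compared with an absorbed-iron requirement. The
  toxicity upper limit for iron is always applied to raw dietary iron,
  since ingested iron is what harms. A `dietary` mode (raw iron against a
  dietary RNI) is available in `diet_config()`.

Portion sizes scale from a reference child aged 1–3 years by
$(\mu_E + 2\sigma_E)/E_{\mathrm{child}}$; groups such as condiments,
sugars, supplements, milk powder, infant foods and breast milk keep fixed
portions. The reference-child portion table and the fixed portions are
editable data with shipped defaults (e.g. 120 g staples, 50 g legumes,
12 g oil per meal for the reference child at 1,000 kcal/day); published
portion tables for specific contexts should replace them in real use.

## Dispersion defaults

The individuals table carries a per-nutrient SD for every adjustable
micronutrient. The shipped synthetic individuals use
$\sigma = 0.1 \times \mathrm{RNI}$, which corresponds to a CV of 12.5% of
the mean requirement — a mid-range value for nutrient requirement
distributions. Energy SDs are set at 10% of the EAR. These are study
conditions of the synthetic data, not package constants: real assessments
supply their own columns.

## Solving, degeneracy and diagnostics

The generic simplex solve goes through `boot::simplex`, with
`pracma::linprog` as a fallback route when the primary solver fails to
converge; every returned optimum is re-verified against all constraint rows
before being accepted. Constraint rows are rescaled so the right-hand side
has magnitude one, which keeps coefficients spanning µg-per-gram
micronutrients and multi-thousand-gram weekly totals in a comfortable
numeric range. `pracma::linprog` draws on the R random stream internally,
so the wrapper pins a fixed local RNG state around it: solves are
bit-for-bit reproducible regardless of ambient state. Ties between
equal-cost optima are broken deterministically by the solver under a fixed
variable ordering (foods sorted by `food_id`); they are not randomised.

Infeasibility is a first-class outcome, not an error. When a problem is
infeasible, `relaxed_solve()` runs a two-stage goal programme: stage one
keeps every upper limit, the total-weight ceiling, group ceilings and
per-food bounds hard, lets each nutrient lower bound fall short by a
proportional slack in $[0,1]$, and minimises total shortfall; stage two
minimises cost at that shortfall optimum. Nutrients that fall short then
report achievement below 100%, and if the total-weight ceiling or an upper
limit binds, the standard warning — that the diet cannot be calculated
because an upper limit was reached — is attached to the solution and
surfaced machine-readably in `warnings.csv`.

For problems with at most three foods, `brute_force_diet()` computes an
independent optimum by enumerating every intersection of $n$ constraint
hyperplanes and keeping the cheapest feasible vertex. Because the feasible
region is bounded (non-negativity plus total weight), a non-empty region
has a vertex and the enumeration is exact. The acceptance suite compares
the simplex route with this oracle on 100 seeded random instances at a
relative cost tolerance of $10^{-4}$ and checks every constraint row at
$10^{-6}$ on scaled rows.

## Market prices and aggregation

Each market record (one trader, one food, one season) contributes a unit
cost: quoted price divided by the mean of up to three sample weights and by
the edible portion factor, per 100 g edible. The seasonal cost is the
unweighted mean over records. The original method does not state a
weighting scheme across traders or markets, so the simplest defensible
estimator — the plain mean of per-record unit costs — was chosen; if market
sizes are known a weighted mean would be a reasonable extension. Zero
prices are legal observations (free or subsidised food). Liquids are
converted to grams by specific gravity at import; the optimisation never
sees millilitres. Internally all costs are currency per gram; "per 100 g"
appears only at I/O boundaries, which removes a whole class of ×100 errors.

Seasonal weekly costs aggregate to annual cost as
$\sum_s w_s\,d_s/7$ over a calendar of 1–6 seasons whose day counts must
sum to exactly 365. Households are solved per member and summed — one LP
per member, not a pooled LP — because pooling would let the solver trade
nutrients between members, which the method does not intend. Standard
families for comparability with household-economy analysis must average
2,100 kcal/person/day; a 2% tolerance accommodates the fact that discrete
member choices cannot hit the target exactly (the shipped five-member
family happens to hit it exactly).

## Affordability

Annual diet cost is expressed as a share of wealth-group annual income,
optionally stacking essential non-food expenditure on top (the cumulative
view used in affordability charts). The income gap is
$\max(0, \mathrm{cost} + \mathrm{NFE} - \mathrm{income})$, clamped at zero
because a surplus is not a negative gap. Affordability is never computed
for the macronutrients diet, which exists only as an analytic reference
point between the energy-only and nutritious diets.

## What the synthetic scenario does and does not emulate

`generate_scenario()` builds a three-market, two-trader, three-season
economy over eleven archetype foods (staples, legumes, a green leafy
vegetable, small dried fish, oil, fresh milk, fruit, eggs, salt) with
seasonal price multipliers, lognormal trader noise and weighed sample
variation, plus the five-member standard family, habit frequencies and four
wealth groups. Archetype profiles are nutritionally plausible for their
class — dried fish rich in calcium and B12, lentils in folate and B1,
leaves in vitamin A and C — but they are synthetic numbers, not food-table
truth, and prices emulate no real country.

Feasibility of the default scenario is guaranteed by construction: before a
scenario is emitted, a designed feasible diet is built for every family
member in every season by a greedy repair heuristic (template energy
shares, then add the densest source of any short nutrient and rebalance
staple energy) and checked against every constraint row without invoking
the LP solver. The `infeasible-calcium` preset removes the dried fish, milk
and egg archetypes and substitutes a calcium-poor leaf so that calcium is
unreachable — the canonical diagnostic case.

Passing tests on this scenario therefore demonstrate the machinery —
formulation, solving, diagnosis, aggregation, reporting — under realistic
magnitudes. They do not validate any real market: real food composition
tables, real price surveys and reviewed portion/requirement data are needed
for substantive conclusions.

## Problem sizes and numerical choices

The shipped test-suite and the acceptance script solve roughly a thousand
LPs: 60-cell assessment grids (5 members × 3 seasons × 4 levels), 100
random 1–3-food oracle comparisons, and assorted toy instances. Individual
problems have ≤ 11 foods and ≈ 25–45 constraint rows and solve in
milliseconds; the full default assessment runs in a few seconds on one
core. Energy-band half-width is $10^{-6}$ relative; feasibility checks use
$10^{-6}$ on scaled rows; the oracle comparison uses $10^{-4}$ relative on
cost. Degenerate inputs — zero body weight, zero-width fat bands, zero
prices, foods missing a seasonal price (excluded with a warning) — are
exercised in the unit tests.

## Known limitations

* Servings are continuous; no integer or palatability modelling.
* Cooking losses and intra-household distribution are out of scope.
* The shipped portion sizes, requirement dispersions and absorption
  factors are placeholder defaults for synthetic work; field use requires
  reviewed tables.
* Whether energy should be a strict equality or a narrow band in the
  original tool is not fully specified; the tolerant-equality reading used
  here is worth flagging to users comparing against other implementations.
* Retrospective and current price records are aggregated identically.
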