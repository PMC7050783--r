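Package: lcdiet
Title: Least-Cost Diet Linear Programming for Nutrition and Food Security
    Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates the lowest possible cost of a diet that meets the
    energy, protein, fat and micronutrient specifications of individuals
    and households from locally priced foods.  Builds and solves a weekly
    linear programme per individual, season and diet level (energy-only,
    macronutrients, nutritious, food-habits nutritious), computes nutrient
    achievement and infeasibility diagnostics, aggregates costs over
    households, seasons and the year, and expresses affordability against
    wealth-group income and non-food expenditure.  Includes percentile-based
    requirement modelling, portion-size scaling from a reference child,
    market price survey aggregation to cost per 100 g edible portion, a
    synthetic market scenario generator for fully reproducible test
    assessments, and a brute-force vertex-enumeration oracle for verifying
    small optimisation problems.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    boot,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    withr,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
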