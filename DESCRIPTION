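Package: dairyflex
Title: Food Pattern Modeling of Dairy Fat Flexibility in Healthy Eating
    Patterns
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@dairyflex.dev",
           role = c("aut", "cre"))
Description: Tools for food pattern modeling of dairy serving substitutions
    in the USDA 2000-kcal Healthy U.S.-Style Eating Pattern. Builds
    consumption-weighted dairy nutrient composites (fat-free, reduced-fat
    and whole-fat milk/cheese/yogurt blends) from per-cup-equivalent food
    records, substitutes servings of them into the reference eating
    pattern, and evaluates the resulting day-level nutrient totals against
    percent-change baselines, macronutrient percent-of-energy limits, and
    Dietary Reference Intake goals (%RDA, %AI, %UL) for sample age-sex
    groups, including saturated-fat (10% of calories) and sodium
    (2,300 mg/d CDRR) threshold screening. Ships the published reference
    tables as plain-text fixtures and a seeded synthetic generator of
    FNDDS-like dairy food records so the full pipeline is testable without
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
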