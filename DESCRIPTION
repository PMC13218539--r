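Package: mealforge
Title: Archetype-Conditioned Meal Generation, RDI Portioning and Food Substitution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns dietary standards into complete meals. Discovers meal
    archetypes from a meal-food-nutrient corpus with density-based clustering,
    generates archetype-conditioned food combinations with a conditional
    variational autoencoder, assigns gram portions to meet per-meal Recommended
    Daily Intake (RDI) targets through an ordered constraint pipeline, and
    recommends few-item meal substitutions along a nutrition-versus-cost
    trade-off frontier. Includes a seeded synthetic corpus generator emulating
    dietary-survey meal structure so the full pipeline is testable without
    external data, plus a nutrient-adequacy metric suite (MAR, MER, AMDR
    compliance, Hill diversity, energy density) with bootstrap and
    false-discovery-rate inference.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    mclust
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
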