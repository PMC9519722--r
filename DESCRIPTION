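Package: standsens
Title: Sensitivity Analysis of Adaptive Forest Management in Simulated
    Beech- and Spruce-Dominated Stands
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Individual-tree simulation of generic beech- and
    spruce-dominated stands on 5-year time steps, with a climate-sensitive
    demographic core (diameter growth, logistic mortality, light- and
    temperature-dependent ingrowth), an empirical single-tree removal
    (harvesting) model, and graded adaptive silvicultural interventions
    (planting, intensified thinning of climatically unsuited species,
    intensified target-diameter harvesting). Computes ten ecosystem-service
    and biodiversity indicators (timber, carbon including deadwood and
    harvested-wood-product pools, tree species and structural diversity,
    deadwood, habitat trees), aggregates them with stakeholder weights, and
    quantifies intervention effect sizes and directions (ANOVA variance
    decomposition) and trade-offs and synergies (Spearman rank correlations)
    over a fully crossed scenario grid.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
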