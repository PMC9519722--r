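# standsens

Simulation-based sensitivity analysis of adaptive forest management in
generic beech- and spruce-dominated stands.

Climate change puts the two commercially dominant Central-European species
— Norway spruce (*Picea abies*) and European beech (*Fagus sylvatica*) —
under pressure at low to mid elevations, and forest managers weigh
*adaptive* interventions: planting climatically better-suited species
(Douglas-fir, oak, silver fir), thinning the unsuited dominant species more
heavily, and harvesting target-diameter trees earlier to shorten rotations.
`standsens` quantifies what such interventions, applied at graded
intensities and crossed with climate scenarios, do to ecosystem service and
biodiversity (ESB) provision at the stand scale. It is aimed at forest
modellers and ecosystem-service analysts who need a transparent,
fully-configurable individual-tree testbed rather than a black-box
simulator.

## What it computes

**Stand dynamics.** One-hectare tree lists are synthesized from Weibull
diameter distributions fitted to median inventory statistics of four stand
classes (beech/spruce x pole/mature; unimodal for pole, two-component
mixture with understorey share $\rho$ for mature). Trees then grow, die and
recruit on 5-year steps:

- growth: $\Delta d = \exp(a_s + b_1\ln d + b_2 d + b_3\,\mathrm{BAL} +
  b_4\ln(\mathrm{BA}+1) + c_s T + b_5\,\mathrm{MI})\cdot\varepsilon$, with
  BAL the basal area of larger trees, MI the precipitation/temperature
  moisture index and $\varepsilon$ mean-one lognormal;
- mortality: 5-year probability
  $\mathrm{logit}^{-1}(m_0 + m_1/d + m_2\,\mathrm{BAL} + m_3\,\mathrm{BA})$;
- ingrowth at the 12-cm calliper:
  $N \sim \mathrm{Poisson}(\lambda_{\max} e^{-k\,\mathrm{BA}}
  e^{w T_\mathrm{winter}})$.

**Management.** A single-tree removal model (inverse-logit in diameter,
increment, stand density and the 10-year harvest interval) is anchored so
the decadal removal probability at baseline covariates is 21.8% (2.4%
yr⁻¹). The *reference* scenario reduces it by 25%; interventions multiply
it further — thinning (x1.15–1.60 on the unsuited species), target-diameter
harvesting (x1.15–1.60 on broadleaves ≥ 60 cm / conifers ≥ 50 cm) — and
planting scenarios add preparatory thinning plus a 100–400 tree cohort of
Douglas-fir/oak/fir entering in 2031 at 12 ± 0.5 cm.

**Indicators and analytics.** Ten indicators per step (growing stock,
harvest, increment; carbon in living biomass, deadwood and four
harvested-wood-product pools with exponential temperature-sensitive decay;
Shannon and structural diversity, deadwood volume, habitat trees > 70 cm)
are min–max scaled and weighted into three ESB aggregates. The fully
crossed design (4 stands x 125 variants x 3 climates, 20 replicates) feeds
ANOVA variance decomposition (relative sums of squares + effect directions)
and per-time-step Spearman trade-off/synergy correlations with
replicate-based confidence bands.

## Worked example

```r
library(standsens)

tg   <- stand_targets("beech_dominated", "mature")
spec <- fit_weibull(tg)
spec
#> <weibull_spec> mature (2 components)
#>   w=0.78 shape=0.532 scale=2.13 location=2.44
#>   w=0.22 shape=3.399 scale=52.45 location=0.00
#>   max rel. error: 4.43% (calliper share 0.30, target 0.38)

st <- sample_stand(spec, tg, seed = 1)
st
#> <stand> beech_dominated / mature, year 2016
#>   live trees: 320  BA: 49.5 m2/ha  QMD: 44.4 cm  GS: 583 m3/ha
#>   deadwood: 25.0 m3/ha  HWP carbon: 0.0 tC/ha

# plant 400 trees/ha with mild extra thinning, strong warming scenario
v  <- management_variant(400, 1.15, 1.00)
tr <- run_scenario("beech_dominated", "mature", v, "strong", seed = 1)
tr[tr$year %in% c(2016, 2036, 2066, 2101),
   c("year", "growing_stock", "harvested_volume", "carbon_living",
     "shannon", "habitat_trees")]
#>  year growing_stock harvested_volume carbon_living shannon habitat_trees
#>  2016         31.64           551.30         11.81    1.18             0
#>  2036        199.21            35.53         70.70    1.60             0
#>  2066        410.49           123.25        138.70    1.60            12
#>  2101        560.63             0.00        179.84    1.57            44
```

The mixture fit reproduces the published diameter statistics (d10, mean,
d90, overstorey QMD) within 4.4% at worst. In the planting run, the 2016
record shows the preparatory thinning (all trees above 30 cm removed, 551
m³/ha harvested), after which the planted Douglas-fir/oak/fir cohort
rebuilds the stand: growing stock and living carbon recover within three
decades, and from mid-century the fast-growing planted trees pass the
70-cm habitat threshold (44 habitat trees/ha by 2101), lifting the
biodiversity indicators.

Full experiments run through `run_experiment()` (configurable grid,
replicates and horizon) and feed `esb_aggregates()`, `relative_change()`,
`anova_decomposition()` and `spearman_tradeoffs()`. A thin CLI over the
same functions lives in `inst/scripts/standsim.R`
(`init-stand`, `grid`, `climate`, `simulate`, `run-experiment`).

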