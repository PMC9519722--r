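---
title: "Simulating adaptive forest management and its effects on ecosystem services"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating adaptive forest management and its effects on ecosystem services}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(standsens)
```

## Scope and design

`standsens` is a simulation-based sensitivity-analysis framework for
adaptive forest management in generic, one-hectare beech- and
spruce-dominated stands typical of low- to mid-elevation forest north of the
Alps. It couples four pieces:

1. **Stand synthesis** — initial tree lists sampled from Weibull diameter
   distributions fitted to published median inventory statistics, with
   configurable species composition, plus synthetic 5-year climate series
   (historical resampling and two warming scenarios).
2. **Demographic core** — individual-tree diameter growth, mortality and
   ingrowth on 5-year steps, climate-sensitive through annual mean
   temperature, winter temperature and a moisture index.
3. **Management** — an empirical single-tree removal model (business-as-usual,
   BAU), its 25%-reduced *reference* variant, and three graded adaptive
   interventions: planting (with preparatory thinning), intensified thinning
   of the climatically unsuited species, and intensified target-diameter
   harvesting.
4. **Indicators and analytics** — ten ecosystem-service-and-biodiversity
   (ESB) indicators aggregated with stakeholder weights into timber
   production, carbon storage and biodiversity values; ANOVA variance
   decomposition of the fully crossed scenario grid; Spearman trade-off and
   synergy correlations over time.

The standard experiment crosses 4 stand classes x 125 management variants
(5 planting x 5 thinning x 5 harvesting levels) x 3 climate scenarios =
1500 scenarios, 20 replicates each, over 18 five-year steps (2016–2101).

## Stand synthesis

### Diameter distributions

Each of the four stand classes (beech/spruce x pole/mature) is described by
median statistics: stems per hectare above and below the 12-cm calliper,
mean diameter, the 10% and 90% diameter quantiles and, for the mature
(bimodal) classes, the overstorey quadratic mean diameter and the
understorey share $\rho$. Pole-stage classes use a single three-parameter
Weibull (shape, scale, location); mature classes a two-component mixture
whose mixing weight equals $\rho$.

Parameters are found by weighted least squares on the relative errors of
the analytic d10, mean, d90 and (mature) overstorey QMD, with Nelder–Mead
on log-transformed parameters from a small set of deterministic restarts; a
fit is rejected if any matched statistic misses its target by more than 5%.
The share of probability mass above the 12-cm calliper, implied by the
ratio of the two printed stem counts, enters the objective as a soft,
down-weighted constraint: it keeps the truncated tree list realistic
without competing with the hard quantile targets.

Sampling draws from the untruncated mixture, discards trees at or below
12 cm and continues until the target stem count above the calliper is
reached, so the fitted shape above the calliper is preserved. Species are
assigned by an independent multinomial draw on fixed stem-share targets
(about 80% spruce in spruce-dominated stands; a beech-led mixture
otherwise); the diameter–species copula of the original stand-generation
method is not reproduced, and the shares are configurable rather than
asserted.

One known artefact: the published class medians are *marginal* medians and
are not jointly consistent — in the mature classes, the implied number of
overstorey trees at the printed overstorey QMD alone yields a basal area
near 50–60 m²/ha, so the sampled mature stands start denser than a typical
median stand. Long-run behaviour is insensitive to the initial state (the
management model drives stands towards its own equilibrium within a few
decades), but early-period absolute levels should be read with this in
mind.

### Climate scenarios

A pool of 30 synthetic annual values (temperature ~7.5 °C, precipitation
~1100 mm, winter temperature derived from the annual value) emulates the
1986–2015 reference period; it is shipped as a plain-text fixture and is
fully replaceable. Each 5-year step resamples one pool year with
replacement. The *moderate* (+0.83 K, −20 mm) and *strong* (+4.95 K,
−221 mm) scenarios add a linear ramp, zero in 2016 and scaled so the mean
offset over the last six steps of the standard horizon (2076–2101,
i.e. the 2071–2100 climatological window) equals the configured
end-of-century delta; only end-period deltas are specified, so a linear
ramp is the most parsimonious shape. Winter temperature receives the same
offset; the moisture index (precipitation over temperature, floored at
1 °C) is recomputed from the ramped values.

## Demographic core

Functional forms are deliberately simple, semi-mechanistic and fully
configurable; all coefficients live in a single versioned parameter object
(`default_params()`, YAML round-trip via `write_params_yaml()`):

* **Growth.** Expected 5-year diameter increment is log-linear in ln(dbh),
  dbh, BAL (basal area of larger trees, the one-sided competition index),
  ln(stand basal area + 1), annual mean temperature and the moisture index,
  with species-group intercepts and temperature slopes, multiplied by
  mean-one lognormal noise (sd 0.15 on the log scale).
* **Mortality.** 5-year death probability is the inverse logit of a linear
  predictor in 1/dbh, BAL and stand basal area: small, suppressed trees in
  dense stands die more, which bounds unmanaged basal area (self-thinning).
* **Ingrowth.** The number of trees crossing the 12-cm calliper per step is
  Poisson with mean `lambda_max * exp(-c * BA) * exp(w * T_winter)` — an
  exponential light-extinction proxy for light availability at the forest
  floor times a winter-temperature response. Recruit species follow the
  live basal-area shares, with the broadleaf share inflated under warm
  winters.
* **Allometry.** Stem volume is a species power law `v = a * dbh^b`;
  biomass is volume x wood density x 1.25 belowground expansion; heights
  follow species Chapman–Richards curves of dbh (used only by the
  structural-diversity indicator).

Operations within a step apply in a fixed, documented order — growth,
height update, mortality, ingrowth — and the step returns an auditable
record (deaths, recruits, gross increment, deadwood inputs); stem counts
conserve exactly.

### Calibration

The empirical growth model that motivated this structure is not published
coefficient-by-coefficient, so the shipped defaults are calibrated against
the two stand-level anchors the original harvesting analysis itself used:

* long-run (> 100 years) growing stock of ≈ 250 m³/ha and basal area of
  ≈ 20 m²/ha under the *unreduced* BAU removal model, and
* ≈ 350 m³/ha under the 25%-reduced reference management,

with the additional directional constraint that warming raises the volume
increment of beech-dominated stands more than that of spruce-dominated
stands (achieved through species temperature slopes: beech 0.05 per K,
spruce 0.01 per K on the log-increment scale). Calibration was done by
iterative simulation on the mature beech class (20 replicates x 150 years);
the decisive levers are the species growth intercepts (level of both
anchors), the diameter slope of the removal model (a steep slope removes
disproportionate volume and depresses the equilibrium) and the density
feedbacks in growth and mortality (they set how strongly the equilibrium
responds to the 25% harvest reduction).

## Management

The raw removal probability of a live tree over a 10-year interval is an
inverse-logit model in diameter (linear + quadratic), expected increment,
stand basal area, ln stems and the interval length. Of the original survey
model's twelve covariates, plot-accessibility and socio-economic variables
are constant for a generic stand and collapse into the intercept, which is
solved exactly so that the probability at baseline covariates equals the
printed 21.8% per decade (2.4% per year via geometric annualisation).

Scenario logic, applied on the *probability* scale (the published
description phrases all modifications as percentage changes of removal
probability; a logit-scale variant would change only large probabilities
materially):

1. reference reduction: `p * 0.75`;
2. thinning multiplier (1.00–1.60) if the tree is the climatically unsuited
   species of its forest type (spruce in spruce-dominated, beech in
   beech-dominated stands) — applied to the dominant unsuited species only,
   the narrower of the two published readings; the alternative (both
   species in both types) is a one-line configuration change;
3. harvesting multiplier (1.00–1.60) if the tree is at or above its target
   diameter (broadleaf ≥ 60 cm, conifer ≥ 50 cm), composing
   multiplicatively with (2);
4. clamped to [0, 1]; planted trees are exempt until they exceed 20 cm dbh
   (configurable), reflecting their low removal probability when small.

Harvests occur every 10 years from 2026. Planting scenarios additionally
run preparatory thinnings (mature: all trees > 30 cm in 2016; pole: 50% of
trees > 12 cm in 2016, 30% > 20 cm in 2026, all > 30 cm in 2031; fractional
removals select uniformly at random — no selection rule is published) and
deliver the planted cohort in 2031: Douglas-fir/oak/silver fir, mixed
evenly in beech-dominated and 40/40/20 in spruce-dominated stands, with
largest-remainder rounding and Normal(12, 0.5) cm entry diameters.

## Indicators

Per 5-year step the simulator records ten indicators: growing stock,
harvested volume and gross volume increment (m³/ha); carbon in living
biomass (51% of conifer, 48% of broadleaf biomass), in deadwood and in four
harvested-wood-product (HWP) pools (tC/ha); Shannon species diversity on
basal-area shares; a structural diversity index (mean of the Shannon
entropies over 5-cm DBH classes and 2-m height classes); deadwood volume;
and habitat trees (live trees with DBH strictly > 70 cm).

Deadwood is tracked in four compartments (coarse/fine x
conifer/broadleaf). Mortality and harvest residue (10% of harvested volume;
the remaining 90% becomes HWP inflow) enter with a 20% fine fraction
(configurable — only the fine/coarse *rate* ratio is published, not the
input split). Each compartment decays exponentially at
`k(T) = k_base * Q10^((T - T_ref)/10)` with broadleaf faster than conifer
and fine compartments exactly five times faster than coarse. HWP carbon is
allocated to sawn timber / panels / paper / energy wood by leaf-type
fractions (defaults 50/15/10/25% conifer, 35/15/20/30% broadleaf) and
decays with pool half-lives of 50/25/2/1 years; both the allocation and the
half-lives are labelled assumptions, as the cited HWP scheme is not printed
in the source. All pool updates return explicit inflow/decay terms so the
carbon ledger closes to numerical precision, and the closures are tested.

Two documented interpretation choices: "volume increment" is *gross*
(survivor growth plus entry volume of recruits), and the structural index
uses the mean-of-entropies formulation rather than the original post-hoc
index formula, which is cited but not reproduced in the source text.
Initial deadwood stocks per class (18–28 m³/ha) are assumptions standing in
for unpublished inventory plot means.

## Analytics

* **Scaling.** Each indicator is min–max scaled to [0, 1] within forest
  type x stage, bounds taken across all scenarios, replicates and time
  steps of the analysed ensemble; a constant indicator maps to 0.5. The
  original scaling footnote is not available in the source text, so this
  choice is isolated behind one function.
* **Aggregation.** Biodiversity = 0.15 Shannon + 0.15 structural + 0.35
  deadwood + 0.35 habitat trees; timber = 0.25 growing stock + 0.5
  harvested volume + 0.25 increment; carbon = the scaled *sum* of the three
  carbon pools (no within-carbon weights are published; scale-then-average
  is available as a configuration switch).
* **Effect sizes.** For each intervention, the scenarios in which only that
  factor deviates from the reference are compared with the matched
  reference run (same climate, same replicate) as percentage change of the
  period-mean ESB; directions are increasing/decreasing when the four level
  means are monotone within a band of 0.5% of the reference mean, else
  undirected. Standard deviations pool replicates and climates.
* **Variance decomposition.** Type-I ANOVA on the balanced grid (equivalent
  to Type-III there) of the per-(scenario, replicate) period-mean ESB, with
  main effects and two-way interactions; shares of total sum of squares sum
  to one by construction, and unbalanced inputs are refused rather than
  silently reweighted. A constant response is reported as all-zero with a
  degeneracy flag.
* **Trade-offs/synergies.** Per time step, Spearman rank correlation of two
  ESB aggregates across the scenarios of a subset, on replicate-mean
  values; 95% pointwise bands come from recomputing the correlation per
  replicate (percentile method — matching the replicate-based band
  construction rather than a Fisher transform).

## Reproducibility and problem sizes

Every stochastic component takes an explicit seed. Scenario runs derive
their seed purely from (root seed, scenario id, replicate) via a
multiplicative hash folded into the 31-bit range, so parallel or resumed
experiments need no shared RNG state, and identical inputs give
bit-identical trajectories.

The test-suite and acceptance problem sizes are chosen to exercise each
claim at the smallest scale that is statistically meaningful: calibration
anchors with 20 replicates x 150 years on one stand class; direction checks
with 20 replicates of four scenario corners on the mature classes;
Monte-Carlo oracles with 10^4 draws; the full 30,000-run experiment is not
rerun in the tests but is reachable through `run_experiment()` on the
default configuration.

## Limitations

* Drought- and disturbance-induced mortality is deliberately absent (as in
  the source analysis, which confines itself to warming effects); warming
  therefore mostly raises productivity.
* The synthetic climate baseline reproduces means and rough variability,
  not observed inter-annual correlation structure or elevation gradients.
* Demographic coefficients are calibrated to two stand-level anchors, not
  fitted to tree-level data; absolute indicator levels are indicative,
  and the framework's value is in *relative* comparisons across the
  crossed design.
* Species composition is assigned independently of diameter at
  initialisation.
* Financial aspects of interventions and carbon-substitution effects are
  out of scope.
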