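#' Tree species diversity (Shannon index)
#'
#' Shannon entropy of the basal-area shares of the species groups present
#' among live trees; 0 for a monoculture or an empty stand.
#'
#' @param stand A `stand`.
#' @return Shannon index (unitless).
#' @export
#' @examples
#' shannon_index(example_stand())
shannon_index <- function(stand) {
  lv <- live_trees(stand)
  if (nrow(lv) == 0) return(0)
  g <- pi * (lv$dbh / 200)^2
  shannon_entropy(tapply(g, lv$species_group, sum))
}

shannon_entropy <- function(w) {
  w <- as.numeric(w[w > 0])
  if (length(w) <= 1) return(0)
  s <- w / sum(w)
  -sum(s * log(s))
}

#' Structural diversity index
#'
#' Mean of two Shannon entropies: over basal-area shares per 5-cm DBH class
#' and over basal-area shares per 2-m height class. Zero when all trees fall
#' into a single diameter class and a single height class.
#'
#' @param stand A `stand` with populated heights.
#' @return Structural diversity index (unitless).
#' @export
structural_index <- function(stand) {
  lv <- live_trees(stand)
  if (nrow(lv) == 0) return(0)
  g <- pi * (lv$dbh / 200)^2
  dbh_class <- floor(lv$dbh / 5)
  h_class <- floor(lv$height / 2)
  h_d <- shannon_entropy(tapply(g, dbh_class, sum))
  h_h <- shannon_entropy(tapply(g, h_class, sum))
  (h_d + h_h) / 2
}

#' Habitat trees
#'
#' Number of large living trees with DBH strictly greater than 70 cm.
#'
#' @param stand A `stand`.
#' @return Count per hectare.
#' @export
habitat_trees <- function(stand) {
  sum(live_trees(stand)$dbh > 70)
}

#' Carbon in living tree biomass
#'
#' Above- plus belowground biomass is volume times species-group wood
#' density times the belowground expansion factor; carbon is 51% of biomass
#' for conifers and 48% for broadleaves.
#'
#' @param stand A `stand`.
#' @param params Parameter list.
#' @return Carbon stock (tC/ha).
#' @export
carbon_living <- function(stand, params = default_params()) {
  lv <- live_trees(stand)
  if (nrow(lv) == 0) return(0)
  sum(tree_biomass(lv$dbh, lv$species_group, params) *
        carbon_fraction(lv$species_group, params))
}

tree_biomass <- function(dbh, species_group, params = default_params()) {
  wd <- .species_vec(params, "wood_density")[species_group]
  tree_volume(dbh, species_group, params) * unname(wd) *
    params$carbon$belowground_expansion
}

carbon_fraction <- function(species_group, params = default_params()) {
  ifelse(leaf_type(species_group) == "conifer",
         params$carbon$frac_conifer, params$carbon$frac_broadleaf)
}

#' Split harvested volume into product and residue
#'
#' 10% of the harvested volume remains in the stand as residue and enters
#' the deadwood pool; 90% leaves the stand as product volume routed to the
#' harvested-wood-product pools.
#'
#' @param volume Harvested volume (m3), vectorised.
#' @param residue_fraction Residue share (default 0.10).
#' @return List with `product` and `residue` (same shape as `volume`;
#'   `product + residue == volume` exactly).
#' @export
#' @examples
#' split_harvest(100)
split_harvest <- function(volume, residue_fraction = 0.10) {
  residue <- residue_fraction * volume
  list(product = volume - residue, residue = residue)
}

#' Deadwood decay over a time step
#'
#' Each of the four compartments (coarse/fine x conifer/broadleaf) receives
#' its input and then decays exponentially at a temperature-dependent rate
#' `k(T) = k_base * Q10^((T - T_ref)/10)`; broadleaf wood decays faster than
#' conifer wood and the fine (< 7 cm) compartments decay five times faster
#' than the coarse compartment of the same leaf type.
#'
#' @param pool Named numeric vector of compartment volumes (m3/ha).
#' @param input Named numeric vector of volume inputs per compartment.
#' @param t_annual Annual mean temperature (deg C) of the step.
#' @param dt Step length (yr); must be > 0.
#' @param params Parameter list.
#' @return List with `pool` (volumes after decay) and `decayed` (volume
#'   lost per compartment; `pool + decayed = old pool + input` exactly).
#' @export
decay_deadwood <- function(pool, input = 0 * pool, t_annual, dt = 5,
                           params = default_params()) {
  stopifnot(dt > 0)
  k <- deadwood_rates(t_annual, params)
  stopifnot(identical(names(pool), names(k)))
  before <- pool + input
  after <- before * exp(-k * dt)
  list(pool = after, decayed = before - after)
}

deadwood_rates <- function(t_annual, params = default_params()) {
  dw <- params$deadwood
  f <- dw$q10^((t_annual - dw$t_ref) / 10)
  c(coarse_conifer = dw$k_conifer * f,
    fine_conifer = 5 * dw$k_conifer * f,
    coarse_broadleaf = dw$k_broadleaf * f,
    fine_broadleaf = 5 * dw$k_broadleaf * f)
}

#' Update the harvested-wood-product carbon pools
#'
#' Product volume (by leaf type) is converted to carbon (volume x wood
#' density of the leaf type's mean species x carbon fraction), allocated to
#' the four pools (sawn timber, wood-based panels, paper and paperboard,
#' energy wood) by leaf-type-specific fractions, and each pool then decays
#' exponentially at its own rate (half-lives in the parameter file).
#'
#' @param pools Named numeric vector of pool carbon stocks (tC/ha).
#' @param product_volume Named numeric vector `c(conifer=, broadleaf=)` of
#'   product volume (m3/ha) entering the pools this step.
#' @param dt Step length (yr).
#' @param params Parameter list.
#' @return List with `pools` (after inflow + decay), `inflow` (tC per
#'   pool) and `decayed` (tC lost per pool); carbon conserves exactly:
#'   `pools + decayed = old pools + inflow`.
#' @export
update_hwp <- function(pools, product_volume = c(conifer = 0, broadleaf = 0),
                       dt = 5, params = default_params()) {
  hw <- params$hwp
  cf <- params$carbon
  dens <- cf$deadwood_density
  inflow_c <- product_volume["conifer"] * dens["conifer"] * cf$frac_conifer
  inflow_b <- product_volume["broadleaf"] * dens["broadleaf"] * cf$frac_broadleaf
  alloc_names <- c("sawn_timber", "panels", "paper", "energy")
  inflow <- unname(inflow_c) * hw$alloc_conifer[alloc_names] +
    unname(inflow_b) * hw$alloc_broadleaf[alloc_names]
  names(inflow) <- alloc_names
  k <- log(2) / hw$half_life[alloc_names]
  before <- pools[alloc_names] + inflow
  after <- before * exp(-k * dt)
  list(pools = after, inflow = inflow, decayed = before - after)
}

#' Carbon stock in the deadwood pool
#'
#' @param deadwood Named compartment volumes (m3/ha).
#' @param params Parameter list.
#' @return Carbon (tC/ha), using leaf-type deadwood densities and carbon
#'   fractions.
#' @export
carbon_deadwood <- function(deadwood, params = default_params()) {
  cf <- params$carbon
  con <- deadwood["coarse_conifer"] + deadwood["fine_conifer"]
  bl <- deadwood["coarse_broadleaf"] + deadwood["fine_broadleaf"]
  unname(con * cf$deadwood_density["conifer"] * cf$frac_conifer +
           bl * cf$deadwood_density["broadleaf"] * cf$frac_broadleaf)
}

#' Assemble the ten-indicator ESB record for one time step
#'
#' @param stand A `stand` (pools already updated for the step).
#' @param harvested_volume Total harvested volume of the step (m3/ha per
#'   5 yr).
#' @param increment_volume Gross volume increment of the step (m3/ha per
#'   5 yr).
#' @param params Parameter list.
#' @return One-row data.frame with `year`, the ten indicators and the raw
#'   carbon total.
#' @export
esb_record <- function(stand, harvested_volume = 0, increment_volume = 0,
                       params = default_params()) {
  met <- stand_metrics(stand, params)
  c_live <- carbon_living(stand, params)
  c_dead <- carbon_deadwood(stand$deadwood, params)
  c_hwp <- sum(stand$hwp)
  data.frame(
    year = stand$year,
    growing_stock = met$growing_stock,
    harvested_volume = harvested_volume,
    volume_increment = increment_volume,
    carbon_living = c_live,
    carbon_deadwood = c_dead,
    carbon_hwp = c_hwp,
    shannon = shannon_index(stand),
    structural = structural_index(stand),
    deadwood_volume = unname(sum(stand$deadwood)),
    habitat_trees = habitat_trees(stand),
    basal_area = met$basal_area,
    stems = met$stems,
    qmd = met$qmd
  )
}
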