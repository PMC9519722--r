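#' Stem volume from diameter
#'
#' Species-group power-law allometry `v = a * dbh^b` (m3, dbh in cm);
#' strictly increasing in dbh.
#'
#' @param dbh Diameter at breast height (cm), vectorised.
#' @param species_group Species group codes, recycled against `dbh`.
#' @param params Parameter list.
#' @return Stem volume (m3) per tree.
#' @export
#' @examples
#' tree_volume(50, "beech")
tree_volume <- function(dbh, species_group, params = default_params()) {
  if (length(dbh) == 0) return(numeric(0))
  a <- .species_vec(params, "vol_a")[species_group]
  b <- .species_vec(params, "vol_b")[species_group]
  unname(a * dbh^b)
}

#' Tree height from diameter
#'
#' Species-group Chapman-Richards curve
#' `h = 1.3 + (hmax - 1.3) * (1 - exp(-hk * dbh))^hp` (m).
#'
#' @inheritParams tree_volume
#' @return Height (m) per tree.
#' @export
tree_height <- function(dbh, species_group, params = default_params()) {
  if (length(dbh) == 0) return(numeric(0))
  hmax <- .species_vec(params, "hmax")[species_group]
  hk <- .species_vec(params, "hk")[species_group]
  hp <- .species_vec(params, "hp")[species_group]
  unname(1.3 + (hmax - 1.3) * (1 - exp(-hk * dbh))^hp)
}

#' Expected 5-year diameter increment
#'
#' Deterministic part of the diameter-growth model: log-linear in ln(dbh),
#' dbh, BAL (basal area of larger trees), ln(stand basal area + 1), annual
#' mean temperature and moisture index, with a species-group intercept and
#' temperature coefficient. The stochastic version multiplies this by
#' lognormal noise (sd `params$growth$sigma` on the log scale).
#'
#' @param dbh Diameter (cm) per live tree.
#' @param species_group Species group per tree.
#' @param bal BAL (m2/ha) per tree.
#' @param basal_area Stand basal area (m2/ha).
#' @param climate_step One row of a climate scenario (list or data.frame row
#'   with `t_annual` and `moisture_index`).
#' @param params Parameter list.
#' @return Expected increment (cm per 5-year step), always >= 0.
#' @export
grow_expected <- function(dbh, species_group, bal, basal_area, climate_step,
                          params = default_params()) {
  if (length(dbh) == 0) return(numeric(0))
  g <- params$growth
  a0 <- .species_vec(params, "growth_intercept")[species_group]
  bt <- .species_vec(params, "growth_temp")[species_group]
  t_ann <- .clamp(climate_step$t_annual, -5, 25)
  mi <- .clamp(climate_step$moisture_index, 0, 500)
  lp <- a0 + g$ln_dbh * log(dbh) + g$dbh * dbh + g$bal * bal +
    g$ln_ba * log(basal_area + 1) + bt * t_ann + g$moisture_index * mi
  unname(exp(lp))
}

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Stochastic 5-year diameter increments for the live trees of a stand
#'
#' @param stand A `stand`.
#' @param climate_step One climate step.
#' @param params Parameter list.
#' @param deterministic If `TRUE`, returns the expected increment without
#'   lognormal noise.
#' @return Increment (cm / 5 yr) per live tree, in tree-list order.
#' @export
grow <- function(stand, climate_step, params = default_params(),
                 deterministic = FALSE) {
  lv <- live_trees(stand)
  ba <- stand_metrics(stand, params)$basal_area
  mu <- grow_expected(lv$dbh, lv$species_group, tree_bal(stand), ba,
                      climate_step, params)
  if (deterministic || params$growth$sigma == 0) return(mu)
  mu * exp(stats::rnorm(length(mu), 0, params$growth$sigma) -
             params$growth$sigma^2 / 2)
}

#' Five-year mortality probability per live tree
#'
#' Inverse-logit of a linear predictor in inverse diameter, BAL and stand
#' basal area; small and heavily shaded trees in dense stands die more.
#'
#' @inheritParams grow
#' @return Probability in [0, 1] per live tree.
#' @export
mortality_probability <- function(stand, params = default_params()) {
  lv <- live_trees(stand)
  if (nrow(lv) == 0) return(numeric(0))
  m <- params$mortality
  ba <- stand_metrics(stand, params)$basal_area
  lp <- m$intercept + m$inv_dbh / lv$dbh + m$bal * tree_bal(stand) + m$ba * ba
  stats::plogis(lp)
}

#' Ingrowth at the 12-cm calliper
#'
#' The number of trees crossing the calliper in a 5-year step is Poisson
#' with mean `lambda_max * exp(-light_ext * basal_area) * w(t_winter)`:
#' light availability decays exponentially with stand basal area and the
#' winter-temperature response `w` is `exp(winter_temp * t_winter)`. Species
#' are drawn proportionally to live basal-area shares, with the broadleaf
#' share inflated by `exp(broadleaf_bonus * t_winter)` under warm winters;
#' an empty stand falls back to the forest-type default composition. New
#' trees enter at 12 cm plus a small uniform jitter with origin
#' `"ingrowth"`.
#'
#' @inheritParams grow
#' @param id_start First tree_id to assign to recruits.
#' @return data.frame of new tree records (possibly zero rows).
#' @export
ingrow <- function(stand, climate_step, params = default_params(),
                   id_start = NULL) {
  ig <- params$ingrowth
  ba <- stand_metrics(stand, params)$basal_area
  tw <- .clamp(climate_step$t_winter, -15, 15)
  lambda <- ig$lambda_max * exp(-ig$light_ext * ba) * exp(ig$winter_temp * tw)
  n <- stats::rpois(1, lambda)
  if (is.null(id_start)) {
    id_start <- if (nrow(stand$trees) > 0) max(stand$trees$tree_id) + 1L else 1L
  }
  if (n == 0) {
    return(stand$trees[0, , drop = FALSE])
  }
  lv <- live_trees(stand)
  if (nrow(lv) > 0) {
    g <- pi * (lv$dbh / 200)^2
    w <- tapply(g, lv$species_group, sum)
    shares <- as.numeric(w) / sum(w)
    names(shares) <- names(w)
  } else {
    shares <- default_species_shares(stand$forest_type)
  }
  bl <- leaf_type(names(shares)) == "broadleaf"
  shares[bl] <- shares[bl] * exp(ig$broadleaf_bonus * tw)
  shares <- shares / sum(shares)
  sp <- sample(names(shares), n, replace = TRUE, prob = shares)
  dbh <- ig$entry_dbh + stats::runif(n, 1e-6, ig$entry_jitter)
  data.frame(
    tree_id = seq.int(id_start, length.out = n),
    species_group = sp,
    dbh = dbh,
    height = tree_height(dbh, sp, params),
    status = rep("live", n),
    origin = rep("ingrowth", n),
    stringsAsFactors = FALSE
  )
}

#' Advance a stand one demographic 5-year step
#'
#' Applies, in fixed order: diameter growth (stochastic), height update,
#' mortality (independent Bernoulli draws at the modelled 5-year
#' probability), then ingrowth. Trees that die change status to `"dead"`
#' and their stem volume (at post-growth diameter) is routed into the
#' deadwood compartments (fine fraction per the configured split). The
#' returned record makes the step's bookkeeping auditable: stem counts
#' conserve exactly (`stems_out = stems_in - deaths + ingrowth`).
#'
#' @param stand A `stand`.
#' @param climate_step One climate step (list/data.frame row).
#' @param params Parameter list.
#' @param seed Optional integer seed set before the stochastic draws.
#' @return List with elements `stand` (advanced 5 years), `deaths`
#'   (data.frame of trees that died), `ingrowth` (data.frame of recruits),
#'   `increment_volume` (m3/ha gross growth of survivors plus entry volume
#'   of recruits), `mortality_volume` (named by leaf type, m3/ha) and
#'   `deadwood_input` (named by compartment, m3/ha).
#' @export
step_stand <- function(stand, climate_step, params = default_params(),
                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  trees <- stand$trees
  live_idx <- which(trees$status == "live")
  vol_before <- tree_volume(trees$dbh[live_idx], trees$species_group[live_idx],
                            params)

  inc <- grow(stand, climate_step, params)
  trees$dbh[live_idx] <- trees$dbh[live_idx] + inc
  trees$height[live_idx] <- tree_height(trees$dbh[live_idx],
                                        trees$species_group[live_idx], params)
  stand$trees <- trees

  p_die <- mortality_probability(stand, params)
  died <- stats::rbinom(length(p_die), 1, p_die) == 1
  dead_rows <- live_idx[died]
  trees$status[dead_rows] <- "dead"
  stand$trees <- trees

  deaths <- trees[dead_rows, , drop = FALSE]
  dead_vol <- tree_volume(deaths$dbh, deaths$species_group, params)
  mortality_volume <- c(conifer = 0, broadleaf = 0)
  if (nrow(deaths) > 0) {
    lt <- leaf_type(deaths$species_group)
    for (l in c("conifer", "broadleaf")) {
      mortality_volume[l] <- sum(dead_vol[lt == l])
    }
  }
  ff <- params$deadwood$fine_fraction
  deadwood_input <- c(
    coarse_conifer = unname(mortality_volume["conifer"]) * (1 - ff),
    fine_conifer = unname(mortality_volume["conifer"]) * ff,
    coarse_broadleaf = unname(mortality_volume["broadleaf"]) * (1 - ff),
    fine_broadleaf = unname(mortality_volume["broadleaf"]) * ff
  )

  recruits <- ingrow(stand, climate_step, params)
  if (nrow(recruits) > 0) {
    stand$trees <- rbind(stand$trees, recruits)
  }

  surv_idx <- live_idx[!died]
  vol_after_surv <- tree_volume(trees$dbh[surv_idx],
                                trees$species_group[surv_idx], params)
  vol_before_surv <- vol_before[!died]
  increment_volume <- sum(vol_after_surv - vol_before_surv) +
    sum(tree_volume(recruits$dbh, recruits$species_group, params))

  stand$year <- stand$year + 5
  list(stand = stand, deaths = deaths, ingrowth = recruits,
       increment_volume = increment_volume,
       mortality_volume = mortality_volume,
       deadwood_input = deadwood_input)
}
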