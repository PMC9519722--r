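#' Default experiment configuration
#'
#' The fully crossed simulation design: 4 generic stands (beech/spruce x
#' pole/mature) x 125 management variants (5 planting x 5 thinning x 5
#' harvesting levels, the reference level included in each factor) x 3
#' climate scenarios = 1500 scenarios, 20 replicates each, over the
#' standard 18-step horizon 2016-2101.
#'
#' @param replicates Replicates per scenario (default 20).
#' @param horizon_years Simulation horizon (default 85 years).
#' @param root_seed Root seed from which every scenario x replicate seed is
#'   derived.
#' @return List of class `experiment_config`.
#' @export
default_config <- function(replicates = 20, horizon_years = 85,
                           root_seed = 1L) {
  structure(list(
    forest_types = c("beech_dominated", "spruce_dominated"),
    stages = c("pole", "mature"),
    planting_levels = c(0, 100, 200, 300, 400),
    thinning_levels = c(1.00, 1.15, 1.30, 1.45, 1.60),
    harvesting_levels = c(1.00, 1.15, 1.30, 1.45, 1.60),
    climates = c("historical", "moderate", "strong"),
    replicates = replicates,
    horizon_years = horizon_years,
    root_seed = as.integer(root_seed)
  ), class = "experiment_config")
}

#' Write / read an experiment configuration as YAML
#'
#' @param config An `experiment_config`.
#' @param path File path.
#' @return `write_config_yaml()` the path invisibly; `read_config_yaml()`
#'   the configuration.
#' @export
write_config_yaml <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "experiment_config")
}

#' Enumerate the full-factorial scenario grid
#'
#' Crosses stands x management variants x climate scenarios in a
#' deterministic order and assigns a deterministic `scenario_id`.
#'
#' @param config An `experiment_config`.
#' @return data.frame with one row per scenario: `scenario_id`,
#'   `forest_type`, `stage`, `planting`, `thinning`, `harvesting`,
#'   `climate`.
#' @export
#' @examples
#' nrow(build_grid(default_config()))  # 1500
build_grid <- function(config = default_config()) {
  g <- expand.grid(
    harvesting = config$harvesting_levels,
    thinning = config$thinning_levels,
    planting = config$planting_levels,
    climate = config$climates,
    stage = config$stages,
    forest_type = config$forest_types,
    stringsAsFactors = FALSE
  )
  g <- g[, c("forest_type", "stage", "planting", "thinning", "harvesting",
             "climate")]
  g$scenario_id <- seq_len(nrow(g))
  g[, c("scenario_id", "forest_type", "stage", "planting", "thinning",
        "harvesting", "climate")]
}

#' Derive a reproducible seed for one scenario x replicate
#'
#' Pure function of (root seed, scenario id, replicate): a multiplicative
#' hash folded into the 31-bit positive integer range, so replicated and
#' parallel runs need no shared RNG state.
#'
#' @param root_seed Integer root seed.
#' @param scenario_id Scenario id.
#' @param replicate Replicate index.
#' @return Positive integer seed < 2^31.
#' @export
derive_seed <- function(root_seed, scenario_id, replicate) {
  h <- (as.double(root_seed) * 2654435761 +
          as.double(scenario_id) * 40503 +
          as.double(replicate) * 97) %% 2147483629
  as.integer(h + 1)
}

# fitted weibull specs depend only on the four stand classes; cache them
.fit_cache <- new.env(parent = emptyenv())

cached_fit <- function(forest_type, stage) {
  key <- paste(forest_type, stage, sep = "|")
  if (is.null(.fit_cache[[key]])) {
    targets <- stand_targets(forest_type, stage)
    .fit_cache[[key]] <- list(spec = fit_weibull(targets), targets = targets)
  }
  .fit_cache[[key]]
}

#' Simulate one scenario replicate
#'
#' Wires the full pipeline: sample the initial stand from the fitted
#' diameter distribution, synthesize the climate series, then advance in
#' 5-year steps applying the demographic core and the management events
#' (preparatory thinning in planting scenarios, decadal harvests from 2026,
#' planting delivery in 2031), updating the deadwood and
#' harvested-wood-product pools, and record the ten ESB indicators at every
#' step. Identical inputs and seed give bit-identical output.
#'
#' @param forest_type,stage Stand class.
#' @param variant A `management_variant`.
#' @param climate_kind `"historical"`, `"moderate"` or `"strong"`.
#' @param seed Integer seed for this run.
#' @param params Parameter list.
#' @param horizon_years Simulation horizon (85 = the standard 18 steps).
#' @param harvest_enabled Set `FALSE` to disable all removals (used in
#'   self-thinning diagnostics).
#' @return data.frame with one row per 5-year step (18 rows for the
#'   standard horizon): the ESB indicators plus `mortality_rate` (annual),
#'   `broadleaf_share` and stand metrics.
#' @export
#' @examples
#' v <- management_variant(0, 1, 1)
#' tr <- run_scenario("beech_dominated", "mature", v, "historical", seed = 7)
#' nrow(tr)  # 18
run_scenario <- function(forest_type, stage, variant, climate_kind, seed,
                         params = default_params(), horizon_years = 85,
                         harvest_enabled = TRUE) {
  fit <- cached_fit(forest_type, stage)
  stand <- sample_stand(fit$spec, fit$targets, seed = seed, params = params)
  climate <- make_climate(climate_kind, seed = seed + 1,
                          horizon_years = horizon_years)
  set.seed(seed + 2)
  mgmt <- params$management
  harvest_years <- seq(mgmt$first_harvest_year, max(climate$period_start_year),
                       by = mgmt$harvest_interval)
  prep_years <- if (variant$planting_n > 0) {
    prep_thin_schedule(stage)$year
  } else numeric(0)

  records <- vector("list", nrow(climate))
  # year-2016 events: preparatory thinning precedes the first record
  harvested_step <- c(conifer = 0, broadleaf = 0)
  if (stand$year %in% prep_years) {
    pt <- preparatory_thin(stand, stand$year, params)
    stand <- pt$stand
    harvested_step <- harvested_step + pt$harvested_volume
  }
  if (sum(harvested_step) > 0) {
    # residue and products of the 2016 preparatory thinning enter the pools
    # undecayed; decay starts with the first 5-year step
    residue0 <- split_harvest(harvested_step)
    stand$deadwood <- stand$deadwood +
      .leaf_to_compartments(residue0$residue, params)
    stand$hwp <- update_hwp(stand$hwp, residue0$product, dt = 1e-12,
                            params = params)$pools
  }
  records[[1]] <- .step_record(stand, harvested_step, 0, 0, 0, params)

  for (i in seq_len(nrow(climate) - 1)) {
    cl <- as.list(climate[i, ])
    stems_before <- stand_metrics(stand, params)$stems
    st <- step_stand(stand, cl, params)
    stand <- st$stand
    harvested_step <- c(conifer = 0, broadleaf = 0)
    yr <- stand$year
    if (harvest_enabled) {
      if (yr %in% prep_years) {
        pt <- preparatory_thin(stand, yr, params)
        stand <- pt$stand
        harvested_step <- harvested_step + pt$harvested_volume
      }
      if (yr %in% harvest_years) {
        hv <- harvest(stand, variant, cl, params)
        stand <- hv$stand
        harvested_step <- harvested_step + hv$harvested_volume
      }
    }
    if (variant$planting_n > 0 && yr == mgmt$planting_year) {
      id0 <- if (nrow(stand$trees) > 0) max(stand$trees$tree_id) + 1L else 1L
      stand$trees <- rbind(stand$trees,
                           plant(variant, forest_type, params, id_start = id0))
    }
    # pool updates over the elapsed 5 years, driven by the period climate
    residue <- split_harvest(harvested_step)
    residue_input <- .leaf_to_compartments(residue$residue, params)
    dw <- decay_deadwood(stand$deadwood, st$deadwood_input + residue_input,
                         cl$t_annual, dt = 5, params = params)
    stand$deadwood <- dw$pool
    hw <- update_hwp(stand$hwp, residue$product, dt = 5, params = params)
    stand$hwp <- hw$pools

    mort_rate <- if (stems_before > 0) {
      1 - (1 - nrow(st$deaths) / stems_before)^(1 / 5)
    } else 0
    records[[i + 1]] <- .step_record(stand, harvested_step,
                                     st$increment_volume, mort_rate,
                                     nrow(st$ingrowth), params)
  }
  do.call(rbind, records)
}

.leaf_to_compartments <- function(by_leaf, params) {
  ff <- params$deadwood$fine_fraction
  c(coarse_conifer = unname(by_leaf["conifer"]) * (1 - ff),
    fine_conifer = unname(by_leaf["conifer"]) * ff,
    coarse_broadleaf = unname(by_leaf["broadleaf"]) * (1 - ff),
    fine_broadleaf = unname(by_leaf["broadleaf"]) * ff)
}

.step_record <- function(stand, harvested_by_leaf, increment_volume,
                         mortality_rate, n_ingrowth, params) {
  rec <- esb_record(stand, sum(harvested_by_leaf), increment_volume, params)
  lv <- live_trees(stand)
  bl_share <- if (nrow(lv) > 0) {
    g <- pi * (lv$dbh / 200)^2
    sum(g[leaf_type(lv$species_group) == "broadleaf"]) / sum(g)
  } else 0
  rec$mortality_rate <- mortality_rate
  rec$broadleaf_share <- bl_share
  rec$n_ingrowth <- n_ingrowth
  rec
}

#' Run a (possibly reduced) full-factorial experiment
#'
#' Simulates every scenario of the grid for the requested number of
#' replicates, with per-run seeds derived purely from (root seed, scenario
#' id, replicate), and returns the long results table (one row per
#' scenario x replicate x year). Reruns with the same configuration are
#' byte-identical.
#'
#' @param config An `experiment_config`; scale the factor levels and
#'   replicates down for smoke tests.
#' @param params Parameter list.
#' @param progress Print a line per scenario.
#' @return data.frame: grid columns + `replicate`, `year` and all step
#'   outputs of [run_scenario()].
#' @export
run_experiment <- function(config = default_config(),
                           params = default_params(), progress = FALSE) {
  grid <- build_grid(config)
  out <- vector("list", nrow(grid) * config$replicates)
  k <- 0
  for (i in seq_len(nrow(grid))) {
    sc <- grid[i, ]
    variant <- management_variant(sc$planting, sc$thinning, sc$harvesting)
    for (r in seq_len(config$replicates)) {
      seed <- derive_seed(config$root_seed, sc$scenario_id, r)
      tr <- run_scenario(sc$forest_type, sc$stage, variant, sc$climate,
                         seed = seed, params = params,
                         horizon_years = config$horizon_years)
      meta <- sc[rep(1, nrow(tr)), , drop = FALSE]
      meta$replicate <- r
      k <- k + 1
      out[[k]] <- cbind(meta, tr, row.names = NULL)
    }
    if (progress) {
      message(sprintf("scenario %d/%d done", i, nrow(grid)))
    }
  }
  do.call(rbind, out[seq_len(k)])
}
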