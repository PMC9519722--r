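#' Management variant
#'
#' An adaptive-management variant is the triple (planting level, thinning
#' multiplier, harvesting multiplier) applied on top of the reference
#' management (the empirical removal model with probabilities reduced by
#' 25%). The reference variant is `(0, 1.00, 1.00)`.
#'
#' @param planting_n Trees planted per hectare: 0, 100, 200, 300 or 400.
#' @param thin_mult Multiplier on the removal probability of the climatically
#'   unsuited species (spruce in spruce-dominated, beech in beech-dominated
#'   stands): 1.00, 1.15, 1.30, 1.45 or 1.60.
#' @param harvest_mult Multiplier on the removal probability of
#'   target-diameter trees (broadleaves >= 60 cm, conifers >= 50 cm DBH):
#'   same levels.
#' @param reference_reduction Fractional reduction of the raw removal
#'   probability defining the reference scenario (default 0.25).
#' @param strict If `TRUE` (default) levels are restricted to the listed
#'   sets.
#' @return List of class `management_variant`.
#' @export
#' @examples
#' management_variant(400, 1.15, 1.00)
management_variant <- function(planting_n = 0, thin_mult = 1.0,
                               harvest_mult = 1.0,
                               reference_reduction = 0.25,
                               strict = TRUE) {
  if (strict) {
    stopifnot(planting_n %in% c(0, 100, 200, 300, 400),
              thin_mult %in% c(1.00, 1.15, 1.30, 1.45, 1.60),
              harvest_mult %in% c(1.00, 1.15, 1.30, 1.45, 1.60))
  }
  structure(list(planting_n = planting_n, thin_mult = thin_mult,
                 harvest_mult = harvest_mult,
                 reference_reduction = reference_reduction,
                 is_reference = planting_n == 0 && thin_mult == 1 &&
                   harvest_mult == 1),
            class = "management_variant")
}

#' Raw single-tree removal probability
#'
#' Inverse-logit removal model over a reduced covariate set: species-group
#' offset, diameter (linear + quadratic), expected diameter increment, stand
#' basal area, ln stem number and the inventory interval. Plot-accessibility
#' covariates of the original survey model collapse into the intercept,
#' which is calibrated so the stand-average 10-year probability at baseline
#' covariates is 21.8% (about 2.4% per year).
#'
#' @param dbh Diameter (cm), vectorised.
#' @param species_group Species group per tree.
#' @param increment Expected diameter increment (cm / 5 yr) per tree.
#' @param basal_area Stand basal area (m2/ha).
#' @param stems Live stem count (n/ha).
#' @param interval_yr Removal interval: 5, 10 or 15 years.
#' @param params Parameter list.
#' @return Removal probability over `interval_yr` per tree, in [0, 1].
#' @export
#' @examples
#' p <- default_params()
#' b <- p$removal$baseline
#' removal_probability(b$dbh, "beech", b$increment, b$ba, b$stems, 10, p)
removal_probability <- function(dbh, species_group, increment, basal_area,
                                stems, interval_yr = 10,
                                params = default_params()) {
  stopifnot(interval_yr %in% c(5, 10, 15))
  if (length(dbh) == 0) return(numeric(0))
  r <- params$removal
  off <- .species_vec(params, "removal_offset")[species_group]
  lp <- r$intercept + off + r$dbh * dbh + r$dbh2 * dbh^2 +
    r$increment * increment + r$ba * basal_area +
    r$ln_stems * log(pmax(stems, 1)) + r$dt * (interval_yr - 10)
  unname(stats::plogis(lp))
}

#' Annualize an interval removal probability
#'
#' Geometric survival compounding: `1 - (1 - p)^(1/interval)`.
#'
#' @param p_interval Probability over the interval, in [0, 1).
#' @param interval_yr Interval length in years.
#' @return Annual probability.
#' @export
#' @examples
#' annualize(0.218, 10)  # ~0.024, i.e. 2.4% per year
annualize <- function(p_interval, interval_yr) {
  if (any(p_interval < 0 | p_interval >= 1)) {
    stop("p_interval must be in [0, 1)")
  }
  1 - (1 - p_interval)^(1 / interval_yr)
}

#' Effective removal probability under a management variant
#'
#' Applies, on the probability scale: the reference reduction
#' (`p * (1 - reference_reduction)`); the thinning multiplier if the tree
#' belongs to the climatically unsuited species of the forest type (spruce
#' in spruce-dominated, beech in beech-dominated stands); the harvesting
#' multiplier if the tree is at or above its target diameter (broadleaf
#' >= 60 cm, conifer >= 50 cm). Multipliers compose multiplicatively and the
#' result is clamped to [0, 1]. Planted trees are exempt (probability 0)
#' until they exceed the configured exemption diameter.
#'
#' @param p_raw Raw removal probability per tree, in [0, 1].
#' @param species_group Species group per tree.
#' @param dbh Diameter (cm) per tree.
#' @param variant A `management_variant`.
#' @param forest_type Stand forest type.
#' @param origin Tree origin (`"planted"` trees may be exempt); defaults to
#'   `"initial"`.
#' @param params Parameter list (target diameters, exemption threshold).
#' @return Effective probability per tree.
#' @export
effective_probability <- function(p_raw, species_group, dbh, variant,
                                  forest_type,
                                  origin = rep("initial", length(p_raw)),
                                  params = default_params()) {
  stopifnot(all(p_raw >= 0 & p_raw <= 1))
  if (length(p_raw) == 0) return(numeric(0))
  m <- params$management
  p <- p_raw * (1 - variant$reference_reduction)
  unsuited <- if (forest_type == "spruce_dominated") "spruce" else "beech"
  p <- ifelse(species_group == unsuited, p * variant$thin_mult, p)
  lt <- leaf_type(species_group)
  target <- (lt == "broadleaf" & dbh >= m$target_dbh_broadleaf) |
    (lt == "conifer" & dbh >= m$target_dbh_conifer)
  p <- ifelse(target, p * variant$harvest_mult, p)
  p <- ifelse(origin == "planted" & dbh <= m$planted_exempt_dbh, 0, p)
  pmin(pmax(p, 0), 1)
}

#' Apply a harvest to a stand
#'
#' Each live tree is removed independently with its effective removal
#' probability at the configured harvest interval; removed trees change
#' status to `"harvested"` and their volumes are returned as the harvest
#' ledger.
#'
#' @param stand A `stand`.
#' @param variant A `management_variant`.
#' @param climate_step Climate step used for the increment covariate of the
#'   removal model (deterministic expected growth).
#' @param params Parameter list.
#' @param interval_yr Harvest interval (default 10 years).
#' @return List with `stand`, `removed` (data.frame of harvested trees) and
#'   `harvested_volume` (named by leaf type, m3/ha).
#' @export
harvest <- function(stand, variant, climate_step, params = default_params(),
                    interval_yr = params$management$harvest_interval) {
  lv <- live_trees(stand)
  hv <- c(conifer = 0, broadleaf = 0)
  if (nrow(lv) == 0) {
    return(list(stand = stand, removed = lv, harvested_volume = hv))
  }
  met <- stand_metrics(stand, params)
  inc <- grow_expected(lv$dbh, lv$species_group, tree_bal(stand),
                       met$basal_area, climate_step, params)
  p_raw <- removal_probability(lv$dbh, lv$species_group, inc,
                               met$basal_area, met$stems, interval_yr, params)
  p_eff <- effective_probability(p_raw, lv$species_group, lv$dbh, variant,
                                 stand$forest_type, lv$origin, params)
  take <- stats::rbinom(nrow(lv), 1, p_eff) == 1
  removed <- lv[take, , drop = FALSE]
  stand$trees$status[stand$trees$tree_id %in% removed$tree_id] <- "harvested"
  if (nrow(removed) > 0) {
    v <- tree_volume(removed$dbh, removed$species_group, params)
    lt <- leaf_type(removed$species_group)
    for (l in c("conifer", "broadleaf")) hv[l] <- sum(v[lt == l])
  }
  list(stand = stand, removed = removed, harvested_volume = hv)
}

# preparatory-thinning schedule: (year, dbh threshold cm, removal fraction)
prep_thin_schedule <- function(stage) {
  if (stage == "mature") {
    data.frame(year = 2016, dbh_gt = 30, fraction = 1.0)
  } else {
    data.frame(year = c(2016, 2026, 2031), dbh_gt = c(12, 20, 30),
               fraction = c(0.5, 0.3, 1.0))
  }
}

#' Preparatory thinning ahead of planting
#'
#' Stage-dependent scheduled removals that clear growing space for planted
#' trees: mature stands lose all trees above 30 cm DBH in 2016; pole-stage
#' stands lose 50% of trees above 12 cm in 2016, 30% above 20 cm in 2026 and
#' all trees above 30 cm in 2031. Fractional removals select uniformly at
#' random among the qualifying trees. Only applied in planting scenarios.
#'
#' @param stand A `stand`.
#' @param year Calendar year; (stage, year) pairs outside the schedule are a
#'   no-op.
#' @param params Parameter list (volumes for the ledger).
#' @return List with `stand`, `removed` and `harvested_volume` (named by
#'   leaf type, m3/ha), as for [harvest()].
#' @export
preparatory_thin <- function(stand, year, params = default_params()) {
  sched <- prep_thin_schedule(stand$stage)
  row <- sched[sched$year == year, , drop = FALSE]
  hv <- c(conifer = 0, broadleaf = 0)
  if (nrow(row) == 0) {
    return(list(stand = stand, removed = stand$trees[0, ],
                harvested_volume = hv))
  }
  lv <- live_trees(stand)
  qual <- lv[lv$dbh > row$dbh_gt, , drop = FALSE]
  n_take <- round(row$fraction * nrow(qual))
  if (n_take == 0) {
    return(list(stand = stand, removed = stand$trees[0, ],
                harvested_volume = hv))
  }
  take_ids <- if (row$fraction >= 1) qual$tree_id else {
    sample(qual$tree_id, n_take)
  }
  removed <- lv[lv$tree_id %in% take_ids, , drop = FALSE]
  stand$trees$status[stand$trees$tree_id %in% take_ids] <- "harvested"
  v <- tree_volume(removed$dbh, removed$species_group, params)
  lt <- leaf_type(removed$species_group)
  for (l in c("conifer", "broadleaf")) hv[l] <- sum(v[lt == l])
  list(stand = stand, removed = removed, harvested_volume = hv)
}

#' Generate planted trees
#'
#' Creates the planted cohort delivered in 2031: Douglas-fir, oak and silver
#' fir, with an even mix in beech-dominated stands and 40/40/20
#' (Douglas-fir/oak/fir) in spruce-dominated stands. Species counts follow
#' largest-remainder rounding so they match the mix exactly; entry diameters
#' are Normal(12, 0.5) cm.
#'
#' @param variant A `management_variant` (uses `planting_n`).
#' @param forest_type Stand forest type.
#' @param params Parameter list.
#' @param id_start First tree_id to assign.
#' @return data.frame of planted tree records (zero rows if
#'   `planting_n = 0`).
#' @export
#' @examples
#' v <- management_variant(400)
#' table(plant(v, "spruce_dominated", id_start = 1)$species_group)
plant <- function(variant, forest_type, params = default_params(),
                  id_start = 1L) {
  n <- variant$planting_n
  empty <- data.frame(tree_id = integer(), species_group = character(),
                      dbh = numeric(), height = numeric(),
                      status = character(), origin = character(),
                      stringsAsFactors = FALSE)
  if (n == 0) return(empty)
  mix <- if (forest_type == "beech_dominated") {
    c(douglas_fir = 1 / 3, oak = 1 / 3, fir = 1 / 3)
  } else {
    c(douglas_fir = 0.4, oak = 0.4, fir = 0.2)
  }
  counts <- largest_remainder(mix * n)
  sp <- rep(names(counts), counts)
  m <- params$management
  dbh <- pmax(stats::rnorm(n, m$entry_dbh_mean, m$entry_dbh_sd), 10)
  data.frame(
    tree_id = seq.int(id_start, length.out = n),
    species_group = sp,
    dbh = dbh,
    height = tree_height(dbh, sp, params),
    status = rep("live", n),
    origin = rep("planted", n),
    stringsAsFactors = FALSE
  )
}

largest_remainder <- function(x) {
  fl <- floor(x)
  rem <- x - fl
  short <- round(sum(x)) - sum(fl)
  if (short > 0) {
    add <- order(rem, decreasing = TRUE)[seq_len(short)]
    fl[add] <- fl[add] + 1
  }
  fl
}
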