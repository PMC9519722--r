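#' Default demographic, management and indicator parameters
#'
#' Returns the shipped default parameterisation of the simulator as a nested
#' named list. The functional forms (log-linear diameter growth, logistic
#' mortality and single-tree removal, Poisson ingrowth with exponential light
#' extinction, power-law volume allometry, Chapman-Richards height curves,
#' exponential temperature-sensitive deadwood and harvested-wood-product
#' decay) are fixed; every coefficient lives in this one object so that
#' alternative calibrations can be swapped in, or round-tripped through YAML
#' with [write_params_yaml()] / [read_params_yaml()].
#'
#' The default calibration anchors the long-run (> 100 yr) growing stock at
#' roughly 250 m3/ha (basal area ~20 m2/ha) under the unreduced
#' business-as-usual removal model and roughly 350 m3/ha under the 25%
#' reduced reference management, and makes the diameter-growth response to
#' warming stronger for beech than for spruce.
#'
#' @section Structure:
#' \describe{
#'   \item{species}{per species group: growth intercept and temperature
#'     coefficient, wood density (t/m3), volume allometry `v = vol_a * dbh^vol_b`,
#'     Chapman-Richards height parameters (`hmax` m, `hk`, `hp`), removal
#'     logit offset.}
#'   \item{growth}{shared diameter-growth slopes on ln(dbh), dbh, BAL,
#'     ln(stand BA + 1), moisture index, plus the lognormal noise sd per
#'     5-year step.}
#'   \item{mortality}{logit coefficients: intercept, inverse diameter,
#'     BAL, stand BA (5-year probability scale).}
#'   \item{ingrowth}{`lambda_max` (trees/ha per 5-yr step at zero basal
#'     area), `light_ext` (per m2/ha basal area), winter-temperature slope,
#'     broadleaf winter-temperature bonus, entry diameter and jitter.}
#'   \item{removal}{single-tree removal logit: diameter (+ quadratic),
#'     increment, stand BA, ln stems and interval terms, with the intercept
#'     calibrated so the 10-year probability at the stated baseline
#'     covariates equals `p10_target` (21.8%).}
#'   \item{management}{reference reduction (0.25), harvest interval and
#'     first harvest year, target diameters (broadleaf >= 60 cm,
#'     conifer >= 50 cm), planted-tree exemption diameter, planting entry
#'     year and entry diameter distribution.}
#'   \item{deadwood}{base decay rates per leaf type (1/yr), Q10 and
#'     reference temperature, fine (< 7 cm) input fraction, initial stocks
#'     (m3/ha) per forest type x stage.}
#'   \item{hwp}{product-pool half-lives (yr) and per-leaf-type allocation
#'     fractions for sawn timber, panels, paper and energy wood.}
#'   \item{carbon}{carbon fractions (conifer 0.51, broadleaf 0.48),
#'     belowground expansion factor, deadwood basic densities.}
#' }
#'
#' @return Nested list of class `standsens_params`.
#' @export
#' @examples
#' p <- default_params()
#' names(p)
#' p$management$reference_reduction
default_params <- function() {
  species <- list(
    spruce          = list(growth_intercept = 0.485, growth_temp = 0.010,
                           wood_density = 0.43, vol_a = 2.0e-4, vol_b = 2.40,
                           hmax = 42, hk = 0.035, hp = 1.20, removal_offset = 0),
    fir             = list(growth_intercept = 0.440, growth_temp = 0.020,
                           wood_density = 0.41, vol_a = 2.0e-4, vol_b = 2.40,
                           hmax = 42, hk = 0.033, hp = 1.20, removal_offset = 0),
    douglas_fir     = list(growth_intercept = 0.770, growth_temp = 0.030,
                           wood_density = 0.45, vol_a = 2.1e-4, vol_b = 2.40,
                           hmax = 50, hk = 0.032, hp = 1.15, removal_offset = 0),
    other_conifer   = list(growth_intercept = 0.360, growth_temp = 0.015,
                           wood_density = 0.45, vol_a = 1.95e-4, vol_b = 2.38,
                           hmax = 35, hk = 0.040, hp = 1.25, removal_offset = 0),
    beech           = list(growth_intercept = 0.260, growth_temp = 0.050,
                           wood_density = 0.68, vol_a = 2.1e-4, vol_b = 2.38,
                           hmax = 38, hk = 0.034, hp = 1.25, removal_offset = 0),
    oak             = list(growth_intercept = 0.290, growth_temp = 0.040,
                           wood_density = 0.65, vol_a = 2.0e-4, vol_b = 2.36,
                           hmax = 34, hk = 0.036, hp = 1.25, removal_offset = 0),
    other_broadleaf = list(growth_intercept = 0.310, growth_temp = 0.030,
                           wood_density = 0.55, vol_a = 1.95e-4, vol_b = 2.35,
                           hmax = 30, hk = 0.045, hp = 1.30, removal_offset = 0)
  )

  p <- list(
    species = species,
    growth = list(
      ln_dbh = 0.55, dbh = -0.013, bal = -0.020, ln_ba = -0.18,
      moisture_index = 5e-4, sigma = 0.15
    ),
    mortality = list(
      intercept = -5.2, inv_dbh = 9.0, bal = 0.020, ba = 0.010
    ),
    ingrowth = list(
      lambda_max = 130, light_ext = 0.085,
      winter_temp = 0.030, broadleaf_bonus = 0.10,
      entry_dbh = 12, entry_jitter = 0.3
    ),
    removal = list(
      intercept = NA_real_,   # filled below from the 21.8% decadal anchor
      dbh = 0.010, dbh2 = -0.5e-4, increment = 0.03,
      ba = 0.004, ln_stems = 0.10, dt = 0.15,
      baseline = list(dbh = 30, increment = 1.5, ba = 30, stems = 400),
      p10_target = 0.218
    ),
    management = list(
      reference_reduction = 0.25,
      harvest_interval = 10, first_harvest_year = 2026,
      target_dbh_broadleaf = 60, target_dbh_conifer = 50,
      planted_exempt_dbh = 20,
      planting_year = 2031, entry_dbh_mean = 12, entry_dbh_sd = 0.5
    ),
    deadwood = list(
      k_conifer = 0.033, k_broadleaf = 0.050, q10 = 2.0, t_ref = 7.5,
      fine_fraction = 0.20,
      initial = list(
        beech_dominated  = list(pole = 20, mature = 25),
        spruce_dominated = list(pole = 18, mature = 28)
      )
    ),
    hwp = list(
      half_life = c(sawn_timber = 50, panels = 25, paper = 2, energy = 1),
      alloc_conifer = c(sawn_timber = 0.50, panels = 0.15,
                        paper = 0.10, energy = 0.25),
      alloc_broadleaf = c(sawn_timber = 0.35, panels = 0.15,
                          paper = 0.20, energy = 0.30)
    ),
    carbon = list(
      frac_conifer = 0.51, frac_broadleaf = 0.48,
      belowground_expansion = 1.25,
      deadwood_density = c(conifer = 0.40, broadleaf = 0.55)
    )
  )
  p$removal$intercept <- .removal_intercept(p)
  class(p) <- "standsens_params"
  p
}

# named 7-vector of one per-species field, for fast per-tree lookup
.species_vec <- function(params, field) {
  vapply(params$species, `[[`, numeric(1), field)
}

# Solve the removal-model intercept so that the predicted 10-year removal
# probability at the baseline covariates equals the decadal anchor (21.8%).
.removal_intercept <- function(p) {
  r <- p$removal
  b <- r$baseline
  lp_no_int <- r$dbh * b$dbh + r$dbh2 * b$dbh^2 + r$increment * b$increment +
    r$ba * b$ba + r$ln_stems * log(b$stems) + r$dt * (10 - 10)
  stats::qlogis(r$p10_target) - lp_no_int
}

#' @export
print.standsens_params <- function(x, ...) {
  cat("standsens simulator parameters\n")
  cat("  species groups:", paste(names(x$species), collapse = ", "), "\n")
  cat("  removal anchor: 10-yr probability", x$removal$p10_target,
      "at baseline covariates\n")
  cat("  reference reduction:", x$management$reference_reduction, "\n")
  invisible(x)
}

#' Validate a parameter list
#'
#' Checks structural completeness and basic numeric sanity (positive rates,
#' probabilities in range, allocation fractions summing to one).
#'
#' @param params Parameter list as returned by [default_params()] or
#'   [read_params_yaml()].
#' @return The validated parameter list, invisibly; stops on problems.
#' @export
validate_params <- function(params) {
  need <- c("species", "growth", "mortality", "ingrowth", "removal",
            "management", "deadwood", "hwp", "carbon")
  miss <- setdiff(need, names(params))
  if (length(miss) > 0) {
    stop("parameter list is missing sections: ", paste(miss, collapse = ", "))
  }
  if (!all(species_groups() %in% names(params$species))) {
    stop("species section must cover all groups: ",
         paste(species_groups(), collapse = ", "))
  }
  sp_fields <- c("growth_intercept", "growth_temp", "wood_density",
                 "vol_a", "vol_b", "hmax", "hk", "hp", "removal_offset")
  for (g in names(params$species)) {
    s <- params$species[[g]]
    if (!all(sp_fields %in% names(s))) {
      stop("species '", g, "' is missing fields: ",
           paste(setdiff(sp_fields, names(s)), collapse = ", "))
    }
    if (s$wood_density <= 0 || s$vol_a <= 0 || s$vol_b <= 0 || s$hmax <= 1.3) {
      stop("species '", g, "': allometric parameters must be positive")
    }
  }
  vals <- unlist(params[c("growth", "mortality", "ingrowth")])
  if (any(!is.finite(vals))) stop("non-finite demographic coefficient")
  if (params$ingrowth$lambda_max < 0) stop("lambda_max must be >= 0")
  if (!is.finite(params$removal$intercept)) {
    stop("removal intercept must be finite (use default_params() to anchor it)")
  }
  rr <- params$management$reference_reduction
  if (rr < 0 || rr >= 1) stop("reference_reduction must be in [0, 1)")
  for (al in c("alloc_conifer", "alloc_broadleaf")) {
    if (abs(sum(params$hwp[[al]]) - 1) > 1e-9) {
      stop("HWP ", al, " fractions must sum to 1")
    }
  }
  if (params$deadwood$k_conifer < 0 || params$deadwood$k_broadleaf < 0) {
    stop("deadwood decay rates must be >= 0")
  }
  cf <- params$carbon
  if (cf$frac_conifer <= 0 || cf$frac_conifer >= 1 ||
      cf$frac_broadleaf <= 0 || cf$frac_broadleaf >= 1) {
    stop("carbon fractions must be in (0, 1)")
  }
  invisible(params)
}

#' Write / read simulator parameters as YAML
#'
#' The whole parameter list serialises to a single YAML document; reading
#' re-validates and restores the class. Named numeric vectors (HWP pools)
#' survive the round trip.
#'
#' @param params Parameter list.
#' @param path File path.
#' @return `write_params_yaml()` the path invisibly; `read_params_yaml()`
#'   the validated parameter list.
#' @export
write_params_yaml <- function(params, path) {
  stripped <- unclass(params)
  # named numeric vectors serialise as YAML maps so the names survive
  for (nm in c("half_life", "alloc_conifer", "alloc_broadleaf")) {
    stripped$hwp[[nm]] <- as.list(stripped$hwp[[nm]])
  }
  stripped$carbon$deadwood_density <- as.list(stripped$carbon$deadwood_density)
  yaml::write_yaml(stripped, path)
  invisible(path)
}

#' @rdname write_params_yaml
#' @export
read_params_yaml <- function(path) {
  p <- yaml::read_yaml(path)
  for (nm in c("half_life", "alloc_conifer", "alloc_broadleaf")) {
    p$hwp[[nm]] <- unlist(p$hwp[[nm]])
  }
  p$carbon$deadwood_density <- unlist(p$carbon$deadwood_density)
  class(p) <- "standsens_params"
  validate_params(p)
  p
}
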