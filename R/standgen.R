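#' Median target statistics of the four generic stand classes
#'
#' Plot-based median statistics (stems per hectare above the 12-cm calliper,
#' mean diameter, 10%/90% diameter quantiles, diameter spread, and for the
#' mature bimodal classes the overstorey quadratic mean diameter and the
#' understorey share rho) describing low- to mid-elevation beech- and
#' spruce-dominated stands north of the Alps, in the pole and mature
#' development stages. These are the targets the Weibull initialiser fits.
#'
#' @param forest_type `"beech_dominated"` or `"spruce_dominated"`.
#' @param stage `"pole"` (unimodal diameter distribution) or `"mature"`
#'   (bimodal).
#' @return List of class `stand_targets` with fields `forest_type`, `stage`,
#'   `stems_per_ha_gt12`, `mean_diameter`, `d10`, `d90`, `spread` (cm),
#'   `t_winter` (deg C), `species_shares`, and for mature stands
#'   `overstorey_qmd` (cm) and `rho`.
#' @export
#' @examples
#' stand_targets("beech_dominated", "mature")
stand_targets <- function(forest_type = c("beech_dominated", "spruce_dominated"),
                          stage = c("pole", "mature")) {
  forest_type <- match.arg(forest_type)
  stage <- match.arg(stage)
  tab <- list(
    beech_dominated = list(
      pole   = list(stems_per_ha_gt12 = 545, stems_per_ha_gt0 = 2827,
                    mean_diameter = 7.21,
                    d10 = 1.50, d90 = 18.0, spread = 31.0),
      mature = list(stems_per_ha_gt12 = 320, stems_per_ha_gt0 = 845,
                    mean_diameter = 14.6,
                    d10 = 2.50, d90 = 51.0, spread = 58.5,
                    overstorey_qmd = 49.9, rho = 0.78)
    ),
    spruce_dominated = list(
      pole   = list(stems_per_ha_gt12 = 835, stems_per_ha_gt0 = 1464,
                    mean_diameter = 15.1,
                    d10 = 5.50, d90 = 24.2, spread = 27.0),
      mature = list(stems_per_ha_gt12 = 340, stems_per_ha_gt0 = 1098,
                    mean_diameter = 15.3,
                    d10 = 2.50, d90 = 50.5, spread = 66.0,
                    overstorey_qmd = 52.8, rho = 0.76)
    )
  )
  t_winter <- c(beech_dominated = 1.13, spruce_dominated = -0.72)
  out <- tab[[forest_type]][[stage]]
  out$forest_type <- forest_type
  out$stage <- stage
  out$t_winter <- unname(t_winter[forest_type])
  out$species_shares <- default_species_shares(forest_type)
  validate_targets(out)
  structure(out, class = "stand_targets")
}

validate_targets <- function(t) {
  stopifnot(t$stems_per_ha_gt12 >= 0, t$d10 >= 0)
  if (t$d90 < t$d10) stop("infeasible targets: d90 < d10")
  if (!(t$d10 <= t$mean_diameter && t$mean_diameter <= t$d90)) {
    stop("infeasible targets: need d10 <= mean <= d90")
  }
  if (abs(sum(t$species_shares) - 1) > 1e-9) {
    stop("species shares must sum to 1")
  }
  if (t$stage == "mature") {
    if (is.null(t$rho) || is.null(t$overstorey_qmd)) {
      stop("mature targets need overstorey_qmd and rho")
    }
    if (t$rho <= 0 || t$rho >= 1) stop("rho must be in (0, 1)")
  }
  invisible(t)
}

#' Default species composition per forest type
#'
#' Fixed stem-share targets used when assigning species to sampled diameters:
#' spruce-dominated stands are about 80% spruce with admixed fir and
#' broadleaves; beech-dominated stands are a beech-led mixture with fir,
#' spruce, oak and other broadleaves. Fully configurable; species are
#' assigned independently of diameter.
#'
#' @param forest_type `"beech_dominated"` or `"spruce_dominated"`.
#' @return Named numeric vector of shares summing to 1.
#' @export
default_species_shares <- function(forest_type = c("beech_dominated",
                                                   "spruce_dominated")) {
  forest_type <- match.arg(forest_type)
  if (forest_type == "beech_dominated") {
    c(beech = 0.55, fir = 0.08, spruce = 0.12, oak = 0.05,
      other_broadleaf = 0.17, other_conifer = 0.03)
  } else {
    c(spruce = 0.80, fir = 0.08, beech = 0.05,
      other_conifer = 0.03, other_broadleaf = 0.04)
  }
}

# ---- three-parameter Weibull (mixture) machinery -------------------------

weibull3_mean <- function(shape, scale, location) {
  location + scale * gamma(1 + 1 / shape)
}

weibull3_sqmean <- function(shape, scale, location) {
  # E[X^2] for X = location + W, W ~ Weibull(shape, scale)
  m1 <- scale * gamma(1 + 1 / shape)
  m2 <- scale^2 * gamma(1 + 2 / shape)
  location^2 + 2 * location * m1 + m2
}

weibull3_cdf <- function(q, shape, scale, location) {
  ifelse(q <= location, 0, stats::pweibull(q - location, shape, scale))
}

weibull3_quantile <- function(p, shape, scale, location) {
  location + stats::qweibull(p, shape, scale)
}

mixture_cdf <- function(q, spec) {
  acc <- 0
  for (i in seq_along(spec$components)) {
    cp <- spec$components[[i]]
    acc <- acc + spec$weights[i] * weibull3_cdf(q, cp$shape, cp$scale, cp$location)
  }
  acc
}

mixture_mean <- function(spec) {
  sum(vapply(seq_along(spec$components), function(i) {
    cp <- spec$components[[i]]
    spec$weights[i] * weibull3_mean(cp$shape, cp$scale, cp$location)
  }, numeric(1)))
}

#' Analytic quantile of a fitted Weibull (mixture) specification
#'
#' For a single component the quantile is closed-form; for a mixture the
#' distribution function is inverted numerically with `uniroot`.
#'
#' @param spec A `weibull_spec` from [fit_weibull()].
#' @param p Probability (vectorised).
#' @return Diameter (cm) at the requested quantile(s).
#' @export
weibull_spec_quantile <- function(spec, p) {
  vapply(p, function(pp) {
    stopifnot(pp > 0, pp < 1)
    if (length(spec$components) == 1) {
      cp <- spec$components[[1]]
      return(weibull3_quantile(pp, cp$shape, cp$scale, cp$location))
    }
    upper <- max(vapply(spec$components, function(cp) {
      weibull3_quantile(1 - 1e-9, cp$shape, cp$scale, cp$location)
    }, numeric(1)))
    stats::uniroot(function(q) mixture_cdf(q, spec) - pp,
                   lower = 0, upper = upper, tol = 1e-8)$root
  }, numeric(1))
}

#' Fit a Weibull diameter-distribution specification to stand targets
#'
#' Pole-stage classes are represented by a single three-parameter Weibull
#' (shape, scale, location), mature classes by a two-component mixture whose
#' mixing weight equals the understorey share `rho`. Parameters are found by
#' weighted least squares on the relative errors of the analytic d10, mean
#' and d90 (plus, for mature classes, the overstorey quadratic mean
#' diameter, i.e. the root mean square diameter of the overstorey
#' component), using Nelder-Mead on log-transformed parameters with a small
#' set of deterministic restarts.
#'
#' @param targets A `stand_targets` object.
#' @param tol Maximum acceptable relative error on any matched statistic
#'   (default 0.05).
#' @return Object of class `weibull_spec`: list with `components` (each
#'   `shape`, `scale`, `location`), `weights`, `stage`, and the fit
#'   diagnostics in `fit` (achieved statistics and relative errors).
#' @export
#' @examples
#' spec <- fit_weibull(stand_targets("spruce_dominated", "pole"))
#' weibull_spec_quantile(spec, 0.9)  # ~ 24.2 cm
fit_weibull <- function(targets, tol = 0.05) {
  validate_targets(targets)
  if (targets$stage == "pole") .fit_unimodal(targets, tol)
  else .fit_bimodal(targets, tol)
}

.spec_stats <- function(spec, targets) {
  out <- c(
    d10 = weibull_spec_quantile(spec, 0.10),
    mean = mixture_mean(spec),
    d90 = weibull_spec_quantile(spec, 0.90)
  )
  if (targets$stage == "mature") {
    cp <- spec$components[[2]]
    out["overstorey_qmd"] <- sqrt(weibull3_sqmean(cp$shape, cp$scale, cp$location))
  }
  # share of stems above the calliper, pinned by the ratio of the printed
  # stem counts (> 12 cm vs > 0 cm); keeps the truncated stand realistic
  out["p_gt12"] <- 1 - mixture_cdf(12, spec)
  out
}

.target_vec <- function(targets) {
  out <- c(d10 = targets$d10, mean = targets$mean_diameter, d90 = targets$d90)
  if (targets$stage == "mature") out["overstorey_qmd"] <- targets$overstorey_qmd
  out["p_gt12"] <- targets$stems_per_ha_gt12 / targets$stems_per_ha_gt0
  out
}

# objective weights: the calliper share is a soft constraint
.stat_weights <- function(stats) {
  w <- rep(1, length(stats))
  names(w) <- names(stats)
  w["p_gt12"] <- 0.15
  w
}

.make_spec <- function(par_list, weights, stage) {
  structure(list(components = par_list, weights = weights, stage = stage),
            class = "weibull_spec")
}

.fit_unimodal <- function(targets, tol) {
  tv <- .target_vec(targets)
  obj <- function(theta) {
    cp <- list(shape = exp(theta[1]), scale = exp(theta[2]),
               location = exp(theta[3]))
    spec <- .make_spec(list(cp), 1, "pole")
    st <- tryCatch(.spec_stats(spec, targets), error = function(e) NULL)
    if (is.null(st) || any(!is.finite(st))) return(1e6)
    sum(.stat_weights(st) * ((st - tv) / tv)^2)
  }
  starts <- list(
    c(log(1.2), log(max(targets$mean_diameter - 0.5 * targets$d10, 1)),
      log(max(0.5 * targets$d10, 0.05))),
    c(log(0.9), log(targets$mean_diameter), log(0.05)),
    c(log(2.0), log(max(targets$d90 - targets$d10, 1)),
      log(max(0.3 * targets$d10, 0.05)))
  )
  .fit_best(starts, obj, function(theta) {
    .make_spec(list(list(shape = exp(theta[1]), scale = exp(theta[2]),
                         location = exp(theta[3]))), 1, "pole")
  }, targets, tol)
}

.fit_bimodal <- function(targets, tol) {
  rho <- targets$rho
  tv <- .target_vec(targets)
  to_spec <- function(theta) {
    under <- list(shape = exp(theta[1]), scale = exp(theta[2]),
                  location = exp(theta[3]))
    over <- list(shape = exp(theta[4]), scale = exp(theta[5]),
                 location = exp(theta[6]))
    .make_spec(list(under, over), c(rho, 1 - rho), "mature")
  }
  obj <- function(theta) {
    spec <- to_spec(theta)
    st <- tryCatch(.spec_stats(spec, targets), error = function(e) NULL)
    if (is.null(st) || any(!is.finite(st))) return(1e6)
    sum(.stat_weights(st) * ((st - tv) / tv)^2)
  }
  m2 <- 0.97 * targets$overstorey_qmd
  m1 <- max((targets$mean_diameter - (1 - rho) * m2) / rho, 0.8)
  starts <- list(
    c(log(1.1), log(max(m1 - 0.3, 0.5)), log(0.2),
      log(5), log(0.45 * m2), log(0.55 * m2)),
    c(log(0.9), log(m1), log(0.05),
      log(8), log(0.30 * m2), log(0.68 * m2)),
    c(log(1.5), log(max(m1 - 1, 0.5)), log(max(0.4 * targets$d10, 0.05)),
      log(3.5), log(0.60 * m2), log(0.40 * m2))
  )
  .fit_best(starts, obj, to_spec, targets, tol)
}

.fit_best <- function(starts, obj, to_spec, targets, tol) {
  best <- NULL
  for (s in starts) {
    fit <- stats::optim(s, obj, method = "Nelder-Mead",
                        control = list(maxit = 4000, reltol = 1e-12))
    # polish from the found optimum
    fit <- stats::optim(fit$par, obj, method = "Nelder-Mead",
                        control = list(maxit = 4000, reltol = 1e-12))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  spec <- to_spec(best$par)
  achieved <- .spec_stats(spec, targets)
  tv <- .target_vec(targets)
  rel_err <- abs(achieved - tv) / tv
  spec$fit <- list(objective = best$value, achieved = achieved,
                   targets = tv, rel_err = rel_err)
  # the hard tolerance applies to the quantile/mean statistics; the calliper
  # share is a soft constraint reported in the diagnostics only
  rel_err <- rel_err[setdiff(names(rel_err), "p_gt12")]
  achieved <- achieved[names(rel_err)]
  tv <- tv[names(rel_err)]
  if (any(rel_err > tol)) {
    stop("weibull fit did not converge to within ", tol * 100, "%: ",
         paste(sprintf("%s=%.3f (target %.3f, err %.1f%%)",
                       names(achieved), achieved, tv, 100 * rel_err),
               collapse = "; "))
  }
  spec
}

#' @export
print.weibull_spec <- function(x, ...) {
  cat(sprintf("<weibull_spec> %s (%d component%s)\n", x$stage,
              length(x$components), if (length(x$components) > 1) "s" else ""))
  for (i in seq_along(x$components)) {
    cp <- x$components[[i]]
    cat(sprintf("  w=%.2f shape=%.3f scale=%.2f location=%.2f\n",
                x$weights[i], cp$shape, cp$scale, cp$location))
  }
  if (!is.null(x$fit)) {
    hard <- x$fit$rel_err[setdiff(names(x$fit$rel_err), "p_gt12")]
    cat("  max rel. error:", sprintf("%.2f%%", 100 * max(hard)),
        sprintf("(calliper share %.2f, target %.2f)\n",
                x$fit$achieved["p_gt12"], x$fit$targets["p_gt12"]))
  }
  invisible(x)
}

#' Draw diameters from a fitted specification
#'
#' @param spec A `weibull_spec`.
#' @param n Number of draws.
#' @return Numeric vector of diameters (cm), untruncated.
#' @export
sample_diameters <- function(spec, n) {
  k <- length(spec$components)
  comp <- if (k == 1) rep(1L, n) else {
    sample.int(k, n, replace = TRUE, prob = spec$weights)
  }
  out <- numeric(n)
  for (i in seq_len(k)) {
    idx <- comp == i
    cp <- spec$components[[i]]
    out[idx] <- cp$location + stats::rweibull(sum(idx), cp$shape, cp$scale)
  }
  out
}

#' Sample a one-hectare initial stand
#'
#' Draws diameters from the fitted (mixture) distribution, discards trees at
#' or below the 12-cm calliper and keeps sampling until the target stem
#' count above the calliper is met, assigns species by a multinomial draw on
#' the target shares, and fills heights from the species height curves.
#'
#' @param spec A `weibull_spec` fitted to `targets`.
#' @param targets A `stand_targets` object.
#' @param seed Integer seed; required for reproducibility.
#' @param params Parameter list (height curves).
#' @param calliper_cm Lower diameter threshold (default 12).
#' @return A `stand` whose live trees all have `dbh > calliper_cm`.
#' @export
#' @examples
#' tg <- stand_targets("beech_dominated", "mature")
#' st <- sample_stand(fit_weibull(tg), tg, seed = 1)
#' stand_metrics(st)$stems  # ~320
sample_stand <- function(spec, targets, seed, params = default_params(),
                         calliper_cm = 12) {
  if (missing(seed) || is.null(seed)) {
    stop("a seed is required to sample a stand (reproducibility contract)")
  }
  set.seed(seed)
  n_target <- round(targets$stems_per_ha_gt12)
  dbh <- numeric(0)
  guard <- 0
  while (length(dbh) < n_target) {
    guard <- guard + 1
    if (guard > 1000) stop("sampling failed to reach the target stem count")
    draw <- sample_diameters(spec, max(2L * n_target, 100L))
    dbh <- c(dbh, draw[draw > calliper_cm])
  }
  dbh <- dbh[seq_len(n_target)]
  shares <- targets$species_shares
  sp <- if (n_target > 0) {
    sample(names(shares), n_target, replace = TRUE, prob = shares)
  } else character(0)
  trees <- data.frame(
    tree_id = seq_len(n_target),
    species_group = sp,
    dbh = dbh,
    height = tree_height(dbh, sp, params),
    status = rep("live", n_target),
    origin = rep("initial", n_target),
    stringsAsFactors = FALSE
  )
  dw0 <- initial_deadwood(targets$forest_type, targets$stage, params)
  new_stand(trees, forest_type = targets$forest_type, stage = targets$stage,
            year = 2016, deadwood = dw0)
}

# Initial deadwood stock split into the four compartments using the
# forest-type conifer share and the configured fine fraction.
initial_deadwood <- function(forest_type, stage, params) {
  total <- params$deadwood$initial[[forest_type]][[stage]]
  shares <- default_species_shares(forest_type)
  con <- sum(shares[leaf_type(names(shares)) == "conifer"])
  ff <- params$deadwood$fine_fraction
  c(coarse_conifer = total * con * (1 - ff),
    fine_conifer = total * con * ff,
    coarse_broadleaf = total * (1 - con) * (1 - ff),
    fine_broadleaf = total * (1 - con) * ff)
}
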