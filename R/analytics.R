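#' Stakeholder weighting scheme for the ESB aggregates
#'
#' Indicator weights used to aggregate the scaled indicators into the three
#' ecosystem-service-and-biodiversity (ESB) values: biodiversity (Shannon
#' 0.15, structural 0.15, deadwood 0.35, habitat trees 0.35), timber
#' production (growing stock 0.25, harvested volume 0.5, increment 0.25);
#' carbon storage is the scaled sum of the three carbon pools (no
#' within-carbon weights).
#'
#' @return List with elements `biodiversity` and `timber` (named weight
#'   vectors summing to 1) and `carbon_rule`.
#' @export
weight_scheme <- function() {
  list(
    biodiversity = c(shannon = 0.15, structural = 0.15,
                     deadwood_volume = 0.35, habitat_trees = 0.35),
    timber = c(growing_stock = 0.25, harvested_volume = 0.50,
               volume_increment = 0.25),
    carbon_rule = "sum_then_scale"
  )
}

#' Min-max scale indicator columns within stand-class groups
#'
#' Each indicator is scaled to [0, 1] within every combination of the
#' grouping columns (by default forest type x development stage), with the
#' bounds taken across all scenarios, replicates and time steps present in
#' the table. An indicator that is constant within a group maps to 0.5.
#'
#' @param results Indicator table (one row per scenario/replicate/year).
#' @param vars Columns to scale.
#' @param by Grouping columns (default `c("forest_type", "stage")`).
#' @param suffix Suffix appended to the scaled column names.
#' @return `results` with the scaled columns appended.
#' @export
scale_indicators <- function(results, vars,
                             by = c("forest_type", "stage"),
                             suffix = "_scaled") {
  stopifnot(all(vars %in% names(results)), all(by %in% names(results)))
  grp <- interaction(results[by], drop = TRUE)
  for (v in vars) {
    x <- results[[v]]
    lo <- stats::ave(x, grp, FUN = min)
    hi <- stats::ave(x, grp, FUN = max)
    sc <- ifelse(hi > lo, (x - lo) / (hi - lo), 0.5)
    results[[paste0(v, suffix)]] <- sc
  }
  results
}

#' Compute the three weighted ESB aggregates
#'
#' Scales the ten indicators (and the summed carbon pool stock) within
#' stand-class groups and appends the weighted aggregates `timber`,
#' `biodiversity` and `carbon` to the table.
#'
#' @param results Raw indicator table from [run_experiment()].
#' @param weights A [weight_scheme()].
#' @param by Grouping columns for the scaling.
#' @return `results` with scaled indicator columns and the three ESB
#'   aggregate columns appended.
#' @export
esb_aggregates <- function(results, weights = weight_scheme(),
                           by = c("forest_type", "stage")) {
  results$carbon_total <- results$carbon_living + results$carbon_deadwood +
    results$carbon_hwp
  vars <- c(names(weights$biodiversity), names(weights$timber), "carbon_total")
  results <- scale_indicators(results, vars, by = by)
  wsum <- function(w) {
    acc <- 0
    for (nm in names(w)) acc <- acc + w[[nm]] * results[[paste0(nm, "_scaled")]]
    acc
  }
  results$biodiversity <- wsum(weights$biodiversity)
  results$timber <- wsum(weights$timber)
  results$carbon <- results$carbon_total_scaled
  results
}

period_bounds <- function(period = c("early", "medium", "late", "all")) {
  period <- match.arg(period)
  switch(period,
         early = c(2016, 2041), medium = c(2046, 2071),
         late = c(2076, 2101), all = c(-Inf, Inf))
}

#' Period means of stand-development variables
#'
#' Means over the early (2016-2041), medium (2046-2071) or late (2076-2101)
#' period of selected columns, grouped by scenario descriptors.
#'
#' @param results Indicator table.
#' @param period `"early"`, `"medium"`, `"late"` or `"all"`.
#' @param vars Columns to average.
#' @param by Grouping columns.
#' @return data.frame of period means with a `period` column.
#' @export
period_means <- function(results, period = "early",
                         vars = c("volume_increment", "mortality_rate",
                                  "broadleaf_share", "shannon"),
                         by = c("forest_type", "stage", "climate")) {
  bounds <- period_bounds(period)
  sub <- results[results$year >= bounds[1] & results$year <= bounds[2], ,
                 drop = FALSE]
  vars <- intersect(vars, names(sub))
  out <- stats::aggregate(sub[vars], sub[intersect(by, names(sub))], mean)
  out$period <- period
  out
}

# mean ESB over a period per (scenario descriptor, replicate), wide by ESB
.scenario_means <- function(results, esb, period = "all") {
  bounds <- period_bounds(period)
  sub <- results[results$year >= bounds[1] & results$year <= bounds[2], ,
                 drop = FALSE]
  keys <- intersect(c("scenario_id", "forest_type", "stage", "planting",
                      "thinning", "harvesting", "climate", "replicate"),
                    names(sub))
  stats::aggregate(sub[esb], sub[keys], mean)
}

#' Intervention effect sizes and directions relative to the reference
#'
#' For each stand class, ESB aggregate and intervention (planting, thinning,
#' harvesting), considers the scenarios in which only that intervention
#' deviates from the reference, computes per (level, climate, replicate) the
#' percentage change of the period-mean ESB against the matched reference
#' run (same climate and replicate), and summarises mean and standard
#' deviation pooled over levels, climates and replicates. The direction is
#' `increasing`/`decreasing` if the per-level means are monotone across the
#' four intervention levels (within a tolerance band of 0.5% of the
#' reference mean), otherwise `undirected`.
#'
#' @param results Indicator table with ESB aggregate columns (see
#'   [esb_aggregates()]).
#' @param esb ESB columns to analyse.
#' @param period Averaging period (default the entire simulation period).
#' @param tol_frac Direction tolerance as a fraction of the reference mean.
#' @return data.frame: forest_type, stage, esb, intervention, mean_change,
#'   sd_change, direction.
#' @export
relative_change <- function(results,
                            esb = c("timber", "biodiversity", "carbon"),
                            period = "all", tol_frac = 0.005) {
  sm <- .scenario_means(results, esb, period)
  factors <- c(planting = "planting", thinning = "thinning",
               harvesting = "harvesting")
  ref_levels <- c(planting = 0, thinning = 1, harvesting = 1)
  out <- list()
  for (ft in unique(sm$forest_type)) for (st in unique(sm$stage)) {
    cls <- sm[sm$forest_type == ft & sm$stage == st, , drop = FALSE]
    if (nrow(cls) == 0) next
    ref <- cls[cls$planting == 0 & cls$thinning == 1 & cls$harvesting == 1, ,
               drop = FALSE]
    for (fac in names(factors)) {
      others <- setdiff(names(factors), fac)
      only <- cls[cls[[fac]] != ref_levels[fac] &
                    cls[[others[1]]] == ref_levels[others[1]] &
                    cls[[others[2]]] == ref_levels[others[2]], , drop = FALSE]
      if (nrow(only) == 0) next
      merged <- merge(only, ref,
                      by = intersect(c("climate", "replicate"), names(cls)),
                      suffixes = c("", "_ref"))
      for (e in esb) {
        chg <- 100 * (merged[[e]] - merged[[paste0(e, "_ref")]]) /
          merged[[paste0(e, "_ref")]]
        lev_means <- tapply(chg, merged[[fac]], mean)
        lev_means <- lev_means[order(as.numeric(names(lev_means)))]
        out[[length(out) + 1]] <- data.frame(
          forest_type = ft, stage = st, esb = e, intervention = fac,
          mean_change = mean(chg), sd_change = stats::sd(chg),
          direction = .direction(lev_means, tol = 100 * tol_frac),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, out)
}

.direction <- function(level_means, tol = 0.5) {
  if (length(level_means) < 2) return("undirected")
  d <- diff(level_means)
  if (all(d >= -tol)) "increasing"
  else if (all(d <= tol)) "decreasing"
  else "undirected"
}

#' ANOVA variance decomposition of intervention and climate effects
#'
#' Fits, for one ESB response summarised as its mean over the simulation
#' period per (scenario, replicate), a Type-I ANOVA with the intervention
#' levels and the climate scenario as factors, including all two-way
#' interactions, on the balanced full-factorial grid (Type-I equals
#' Type-III there). Reports each term's share of the total sum of squares
#' plus the residual share, and a per-factor direction from the monotonicity
#' of the level means.
#'
#' @param results Indicator table with ESB aggregates.
#' @param esb Response column.
#' @param include_planting If `FALSE`, scenarios with planting are removed
#'   before the decomposition.
#' @param period Averaging period.
#' @return data.frame with columns `term`, `rel_ss`, `direction`; attribute
#'   `degenerate` is `TRUE` when the response is constant (all shares 0).
#' @export
anova_decomposition <- function(results, esb = "timber",
                                include_planting = TRUE, period = "all") {
  sm <- .scenario_means(results, esb, period)
  if (!include_planting) sm <- sm[sm$planting == 0, , drop = FALSE]
  facs <- intersect(c("planting", "thinning", "harvesting", "climate"),
                    names(sm))
  facs <- facs[vapply(facs, function(f) length(unique(sm[[f]])) > 1,
                      logical(1))]
  if (length(facs) == 0) stop("no varying factors in the results")
  counts <- table(sm[facs])
  if (length(unique(as.vector(counts))) != 1 || any(counts == 0)) {
    stop("unbalanced design: the decomposition assumes a full balanced grid")
  }
  y <- sm[[esb]]
  tot <- sum((y - mean(y))^2)
  dirs <- vapply(facs, function(f) {
    lm_ <- tapply(y, sm[[f]], mean)
    if (f != "climate") lm_ <- lm_[order(as.numeric(names(lm_)))]
    .direction(lm_, tol = 0.005 * max(abs(mean(y)), 1e-12))
  }, character(1))
  if (tot < 1e-12) {
    out <- data.frame(term = c(facs, "residual"),
                      rel_ss = 0, direction = c(dirs[facs], NA),
                      stringsAsFactors = FALSE)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  dat <- sm
  for (f in facs) dat[[f]] <- factor(dat[[f]])
  main <- paste(facs, collapse = " + ")
  form <- stats::as.formula(paste0(esb, " ~ (", main, ")^2"))
  fit <- stats::aov(form, data = dat)
  ss <- summary(fit)[[1]][["Sum Sq"]]
  terms <- trimws(rownames(summary(fit)[[1]]))
  out <- data.frame(term = terms, rel_ss = ss / sum(ss),
                    stringsAsFactors = FALSE)
  out$term[out$term == "Residuals"] <- "residual"
  out$direction <- NA_character_
  out$direction[match(facs, out$term)] <- dirs[facs]
  attr(out, "degenerate") <- FALSE
  out
}

#' Spearman trade-off / synergy correlation at one time step
#'
#' Correlates two ESB aggregates across the scenarios of a subset at one
#' simulation year, using replicate-mean values per scenario. The 95%
#' pointwise confidence band is obtained by recomputing the correlation
#' separately for every replicate and taking the 2.5/97.5 percentiles; the
#' significance flag comes from the rank-correlation test on the
#' replicate-mean values.
#'
#' @param results Indicator table with ESB aggregates.
#' @param pair Character vector of two ESB columns.
#' @param year Simulation year.
#' @param subset Optional logical vector (recycled against `results` rows)
#'   restricting the scenario subset, e.g. planting scenarios only.
#' @return One-row data.frame: `year`, `rho`, `lower`, `upper`, `p_value`,
#'   `significant`.
#' @export
spearman_tradeoffs <- function(results, pair = c("timber", "biodiversity"),
                               year, subset = NULL) {
  stopifnot(length(pair) == 2)
  sub <- results[results$year == year, , drop = FALSE]
  if (!is.null(subset)) sub <- sub[subset[results$year == year], , drop = FALSE]
  if (nrow(sub) < 3) stop("need at least 3 scenarios at the requested year")
  keys <- intersect(c("scenario_id", "planting", "thinning", "harvesting",
                      "climate"), names(sub))
  agg <- stats::aggregate(sub[pair], sub[keys], mean)
  rho <- stats::cor(agg[[pair[1]]], agg[[pair[2]]], method = "spearman")
  test <- suppressWarnings(
    stats::cor.test(agg[[pair[1]]], agg[[pair[2]]], method = "spearman")
  )
  reps <- if ("replicate" %in% names(sub)) unique(sub$replicate) else NULL
  band <- c(NA_real_, NA_real_)
  if (!is.null(reps) && length(reps) >= 2) {
    rhos <- vapply(reps, function(r) {
      s <- sub[sub$replicate == r, , drop = FALSE]
      a <- stats::aggregate(s[pair], s[keys], mean)
      suppressWarnings(stats::cor(a[[pair[1]]], a[[pair[2]]],
                                  method = "spearman"))
    }, numeric(1))
    band <- stats::quantile(rhos, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  }
  data.frame(year = year, rho = rho, lower = band[1], upper = band[2],
             p_value = test$p.value, significant = test$p.value < 0.05)
}
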