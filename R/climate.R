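#' Baseline climate pool
#'
#' Thirty synthetic annual values (mean annual temperature, annual
#' precipitation sum, mean winter temperature) emulating the 1986-2015
#' reference-period statistics of the study region (about 7.5 deg C and
#' 1100 mm at low to mid elevations north of the Alps). Shipped as a small
#' plain-text fixture; the scenario generator resamples from this pool.
#'
#' @param path Optional path to an alternative pool CSV with columns
#'   `year`, `t_annual`, `p_annual`, `t_winter`.
#' @return data.frame with one row per baseline year.
#' @export
climate_baseline <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "climate_baseline_synthetic.csv",
                        package = "standsens", mustWork = TRUE)
  }
  utils::read.csv(path, stringsAsFactors = FALSE)
}

# End-of-century scenario offsets vs the baseline mean (K, mm).
climate_deltas <- function(kind) {
  switch(kind,
         historical = c(dt = 0, dp = 0),
         moderate = c(dt = 0.83, dp = -20),
         strong = c(dt = 4.95, dp = -221),
         stop("unknown climate scenario kind: ", kind))
}

#' Synthesize a climate scenario series
#'
#' Builds a 5-year-step climate series starting in 2016 by resampling the
#' baseline pool with replacement. The `historical` scenario is the pure
#' resample; `moderate` and `strong` add a linear warming/drying ramp
#' (starting at zero in 2016) scaled so that the mean offset over the last
#' six steps of the standard 2016-2101 horizon (i.e. the 2071-2100 window)
#' equals +0.83 K / -20 mm (moderate) or +4.95 K / -221 mm (strong). Winter
#' temperature receives the same temperature offset; the moisture index
#' (precipitation / temperature, an inverse drought proxy) is recomputed
#' from the ramped values.
#'
#' @param kind `"historical"`, `"moderate"` or `"strong"`.
#' @param seed Integer seed for the resampling.
#' @param horizon_years Length of the series in years (>= 85; 85 gives the
#'   standard 18 steps 2016-2101, longer horizons extend the ramp linearly
#'   and are used for long-run calibration).
#' @param baseline Baseline pool data.frame (see [climate_baseline()]).
#' @param start_year First step year.
#' @return Object of class `climate_scenario`: data.frame with columns
#'   `period_start_year`, `t_annual`, `p_annual`, `t_winter`,
#'   `moisture_index`, plus attributes `kind` and `deltas`.
#' @export
#' @examples
#' cl <- make_climate("strong", seed = 1)
#' nrow(cl)  # 18 steps 2016..2101
make_climate <- function(kind = c("historical", "moderate", "strong"),
                         seed, horizon_years = 85,
                         baseline = climate_baseline(),
                         start_year = 2016) {
  kind <- match.arg(kind)
  if (missing(seed) || is.null(seed)) {
    stop("a seed is required to synthesize a climate scenario")
  }
  if (horizon_years < 85) stop("horizon_years must be >= 85")
  deltas <- climate_deltas(kind)
  years <- seq(start_year, start_year + horizon_years, by = 5)
  stopifnot(length(years) >= 18)
  set.seed(seed)
  idx <- sample.int(nrow(baseline), length(years), replace = TRUE)
  # ramp normalisation: mean of the last six standard-horizon step years
  # (2076..2101 for a 2016 start) minus the start year
  std_last6 <- mean(start_year + 5 * (12:17)) - start_year
  ramp <- (years - start_year) / std_last6
  t_annual <- baseline$t_annual[idx] + deltas["dt"] * ramp
  p_annual <- pmax(baseline$p_annual[idx] + deltas["dp"] * ramp, 0)
  t_winter <- baseline$t_winter[idx] + deltas["dt"] * ramp
  out <- data.frame(
    period_start_year = years,
    t_annual = t_annual,
    p_annual = p_annual,
    t_winter = t_winter,
    moisture_index = moisture_index(p_annual, t_annual)
  )
  attr(out, "kind") <- kind
  attr(out, "deltas") <- deltas
  class(out) <- c("climate_scenario", "data.frame")
  out
}

#' Moisture index
#'
#' Ratio of annual precipitation sum to annual mean temperature, used as an
#' inverse drought proxy; the temperature is floored at 1 deg C to keep the
#' ratio finite and non-negative.
#'
#' @param p_annual Annual precipitation sum (mm).
#' @param t_annual Annual mean temperature (deg C).
#' @return Moisture index (mm per deg C).
#' @export
moisture_index <- function(p_annual, t_annual) {
  pmax(p_annual, 0) / pmax(t_annual, 1)
}

#' Export a climate series to CSV
#'
#' @param climate A `climate_scenario`.
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_climate_csv <- function(climate, path) {
  out <- data.frame(year = climate$period_start_year,
                    t_annual = climate$t_annual,
                    p_annual = climate$p_annual,
                    t_winter = climate$t_winter,
                    moisture_index = climate$moisture_index)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
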