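# shared fixtures: all built in code, no stored data

# a stand with explicitly chosen diameters (single species by default)
make_stand <- function(dbh, species = "beech", height = NULL,
                       forest_type = "beech_dominated", stage = "mature",
                       origin = "initial", status = "live") {
  n <- length(dbh)
  trees <- data.frame(
    tree_id = seq_len(n),
    species_group = rep_len(species, n),
    dbh = dbh,
    height = if (is.null(height)) tree_height(dbh, rep_len(species, n))
             else rep_len(height, n),
    status = rep_len(status, n),
    origin = rep_len(origin, n),
    stringsAsFactors = FALSE
  )
  new_stand(trees, forest_type = forest_type, stage = stage)
}

# parameters with all demographic stochasticity / rates stripped, as a base
# for targeted single-process tests
quiet_params <- function() {
  p <- default_params()
  for (g in names(p$species)) {
    p$species[[g]]$growth_intercept <- -1e9   # ~zero growth
    p$species[[g]]$growth_temp <- 0
  }
  p$growth$sigma <- 0
  p$growth$moisture_index <- 0
  p$mortality$intercept <- -1e9               # no mortality
  p$ingrowth$lambda_max <- 0                  # no ingrowth
  p
}

# set every slope of the growth model to zero and the intercept to log(inc)
flat_growth_params <- function(inc = 1) {
  p <- quiet_params()
  p$growth$ln_dbh <- 0
  p$growth$dbh <- 0
  p$growth$bal <- 0
  p$growth$ln_ba <- 0
  p$growth$moisture_index <- 0
  for (g in names(p$species)) {
    p$species[[g]]$growth_intercept <- log(inc)
    p$species[[g]]$growth_temp <- 0
  }
  p
}

# one representative climate step at baseline conditions
baseline_step <- function() {
  list(period_start_year = 2016, t_annual = 7.5, p_annual = 1100,
       t_winter = 0.2, moisture_index = 1100 / 7.5)
}
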