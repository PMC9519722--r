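# small synthetic results tables exercise the statistical machinery without
# running the simulator

fake_results <- function(levels = c(0, 100, 200, 300, 400),
                         climates = c("historical", "moderate", "strong"),
                         replicates = 2, years = seq(2016, 2101, 5),
                         response = function(pl, th, ha, cl, rep, yr) pl) {
  g <- expand.grid(planting = levels, thinning = c(1, 1.3),
                   harvesting = c(1, 1.3), climate = climates,
                   replicate = seq_len(replicates), year = years,
                   stringsAsFactors = FALSE)
  g$forest_type <- "beech_dominated"
  g$stage <- "mature"
  g$scenario_id <- as.integer(interaction(g$planting, g$thinning,
                                          g$harvesting, g$climate, drop = TRUE))
  g$timber <- mapply(response, g$planting, g$thinning, g$harvesting,
                     g$climate, g$replicate, g$year)
  g
}

test_that("min-max scaling maps bounds to 0/1, constants to 0.5, and is affine-invariant", {
  d <- data.frame(forest_type = "a", stage = rep(c("x", "y"), each = 4),
                  v = c(1, 3, 5, 9, 2, 2, 2, 2))
  s <- scale_indicators(d, "v")
  expect_equal(s$v_scaled[1:4], c(0, 0.25, 0.5, 1))
  expect_equal(s$v_scaled[5:8], rep(0.5, 4))  # constant within group
  d2 <- d; d2$v <- 7 * d$v - 3                # affine transformation
  expect_equal(scale_indicators(d2, "v")$v_scaled, s$v_scaled)
})

test_that("ESB aggregation applies the stakeholder weights", {
  w <- weight_scheme()
  expect_equal(sum(w$biodiversity), 1)
  expect_equal(sum(w$timber), 1)
  # two rows spanning the scaling range: first row scales to (1, 0, 1)
  base <- data.frame(
    forest_type = "beech_dominated", stage = "mature",
    growing_stock = c(400, 100), harvested_volume = c(0, 50),
    volume_increment = c(40, 10),
    carbon_living = c(100, 50), carbon_deadwood = c(5, 5),
    carbon_hwp = c(10, 0),
    shannon = c(1, 1), structural = c(2, 2),
    deadwood_volume = c(20, 20), habitat_trees = c(3, 3)
  )
  agg <- esb_aggregates(base)
  expect_equal(agg$timber[1], 0.25 * 1 + 0.5 * 0 + 0.25 * 1)
  expect_equal(agg$timber[2], 0.5)
  # constant biodiversity indicators all scale to 0.5 -> aggregate 0.5
  expect_equal(agg$biodiversity, c(0.5, 0.5))
  # carbon is the scaled sum of the three pools
  expect_equal(agg$carbon, c(1, 0))
})

test_that("relative change is zero against an identical reference and directions classify", {
  r0 <- fake_results(response = function(pl, th, ha, cl, rep, yr) 10)
  rc0 <- relative_change(r0, esb = "timber")
  expect_true(all(abs(rc0$mean_change) < 1e-12))

  # monotone response over planting levels -> increasing
  r1 <- fake_results(response = function(pl, th, ha, cl, rep, yr) 10 + pl / 50)
  rc1 <- relative_change(r1, esb = "timber")
  expect_equal(rc1$direction[rc1$intervention == "planting"], "increasing")

  # non-monotone level means -> undirected
  bump <- c(`0` = 10, `100` = 12, `200` = 10.5, `300` = 14, `400` = 11)
  r2 <- fake_results(response = function(pl, th, ha, cl, rep, yr)
    unname(bump[as.character(pl)]))
  rc2 <- relative_change(r2, esb = "timber")
  expect_equal(rc2$direction[rc2$intervention == "planting"], "undirected")

  # decreasing response
  r3 <- fake_results(response = function(pl, th, ha, cl, rep, yr) 20 - pl / 100)
  rc3 <- relative_change(r3, esb = "timber")
  expect_equal(rc3$direction[rc3$intervention == "planting"], "decreasing")
})

test_that("ANOVA shares sum to one and isolate a single-factor signal", {
  set.seed(99)
  r <- fake_results(response = function(pl, th, ha, cl, rep, yr)
    pl + rnorm(1, 0, 0.5))
  dec <- anova_decomposition(r, esb = "timber")
  expect_equal(sum(dec$rel_ss), 1, tolerance = 1e-9)
  expect_gte(dec$rel_ss[dec$term == "planting"], 0.95)
  expect_equal(dec$direction[dec$term == "planting"], "increasing")
  expect_false(attr(dec, "degenerate"))
})

test_that("ANOVA handles constant responses and refuses unbalanced designs", {
  r <- fake_results(response = function(pl, th, ha, cl, rep, yr) 42)
  dec <- anova_decomposition(r, esb = "timber")
  expect_true(attr(dec, "degenerate"))
  expect_true(all(dec$rel_ss == 0))

  r2 <- fake_results(response = function(pl, th, ha, cl, rep, yr) pl)
  r2 <- r2[!(r2$planting == 400 & r2$thinning == 1.3), ]
  expect_error(anova_decomposition(r2, esb = "timber"), "unbalanced")
})

test_that("excluding planting scenarios drops the planting factor", {
  set.seed(7)
  r <- fake_results(response = function(pl, th, ha, cl, rep, yr)
    pl + 2 * th + rnorm(1, 0, 0.1))
  dec <- anova_decomposition(r, esb = "timber", include_planting = FALSE)
  expect_false("planting" %in% dec$term)
  expect_equal(sum(dec$rel_ss), 1, tolerance = 1e-9)
  expect_gt(dec$rel_ss[dec$term == "thinning"], 0.5)
})

test_that("Spearman correlations hit +-1 on constructed rankings and stay small under noise", {
  r <- fake_results(levels = c(0, 100, 200, 300, 400), replicates = 3)
  r$biodiversity <- r$timber + 1          # identical rankings
  out <- spearman_tradeoffs(r, c("timber", "biodiversity"), year = 2016)
  expect_equal(out$rho, 1)
  r$biodiversity <- -r$timber             # reversed rankings
  out2 <- spearman_tradeoffs(r, c("timber", "biodiversity"), year = 2016)
  expect_equal(out2$rho, -1)
  expect_true(out$rho >= -1 && out$rho <= 1)

  # independent noise: mean |rho| across seeds stays near zero
  set.seed(123)
  rhos <- replicate(30, {
    rn <- fake_results(replicates = 1, years = 2016,
                       response = function(pl, th, ha, cl, rep, yr) rnorm(1))
    rn$biodiversity <- rnorm(nrow(rn))
    spearman_tradeoffs(rn, c("timber", "biodiversity"), year = 2016)$rho
  })
  expect_lt(abs(mean(rhos)), 0.1)
})

test_that("Spearman is invariant under monotone transforms and bands come from replicates", {
  r <- fake_results(replicates = 4,
                    response = function(pl, th, ha, cl, rep, yr)
                      pl + 0.1 * rep)
  r$biodiversity <- exp(r$timber / 100)   # monotone transform
  out <- spearman_tradeoffs(r, c("timber", "biodiversity"), year = 2021)
  expect_equal(out$rho, 1)
  expect_false(is.na(out$lower))
  expect_true(out$lower <= out$rho && out$rho <= out$upper)
})

test_that("period means cover the documented disjoint windows", {
  r <- fake_results(response = function(pl, th, ha, cl, rep, yr) yr)
  r$volume_increment <- r$year
  early <- period_means(r, "early", vars = "volume_increment",
                        by = c("forest_type", "stage"))
  expect_equal(early$volume_increment, mean(seq(2016, 2041, 5)))
  med <- period_means(r, "medium", vars = "volume_increment",
                      by = c("forest_type", "stage"))
  expect_equal(med$volume_increment, mean(seq(2046, 2071, 5)))
  late <- period_means(r, "late", vars = "volume_increment",
                       by = c("forest_type", "stage"))
  expect_equal(late$volume_increment, mean(seq(2076, 2101, 5)))
  # the three windows partition no step twice
  yrs <- seq(2016, 2101, 5)
  in_early <- yrs >= 2016 & yrs <= 2041
  in_med <- yrs >= 2046 & yrs <= 2071
  in_late <- yrs >= 2076 & yrs <= 2101
  expect_true(all(in_early + in_med + in_late <= 1))
  expect_equal(sum(in_early), 6)
})
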