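test_that("annualize follows geometric survival compounding", {
  expect_equal(annualize(0, 10), 0)
  expect_equal(annualize(0.5, 1), 0.5)
  expect_equal(annualize(0.19, 10), 1 - (1 - 0.19)^0.1)
  expect_error(annualize(1, 10), "in \\[0, 1\\)")
})

test_that("removal model hits the decadal anchor at baseline covariates", {
  p <- default_params()
  b <- p$removal$baseline
  pr <- removal_probability(b$dbh, "beech", b$increment, b$ba, b$stems, 10, p)
  expect_equal(pr, 0.218, tolerance = 1e-10)
  # monotone in diameter (positive linear term dominates at these sizes)
  pr2 <- removal_probability(c(20, 30, 45), rep("beech", 3), b$increment,
                             b$ba, b$stems, 10, p)
  expect_true(all(diff(pr2) > 0))
  expect_error(removal_probability(30, "beech", 1, 30, 400, 7, p))
})

test_that("effective probability composes reduction and multipliers", {
  p <- default_params()
  ref <- management_variant(0, 1, 1)
  expect_equal(
    effective_probability(0.2, "beech", 30, ref, "spruce_dominated", params = p),
    0.15)
  # thinning multiplier on the climatically unsuited species only
  v <- management_variant(0, 1.60, 1)
  expect_equal(
    effective_probability(0.2, "spruce", 30, v, "spruce_dominated", params = p),
    0.15 * 1.60)
  expect_equal(
    effective_probability(0.2, "beech", 30, v, "spruce_dominated", params = p),
    0.15)
  expect_equal(
    effective_probability(0.2, "beech", 30, v, "beech_dominated", params = p),
    0.15 * 1.60)
})

test_that("target-diameter boundaries are inclusive at 60 (broadleaf) and 50 (conifer)", {
  p <- default_params()
  v <- management_variant(0, 1, 1.60)
  eb <- effective_probability(c(0.2, 0.2), c("beech", "beech"), c(59.9, 60.0),
                              v, "spruce_dominated", params = p)
  expect_equal(eb, c(0.15, 0.15 * 1.60))
  ec <- effective_probability(c(0.2, 0.2), c("fir", "fir"), c(49.9, 50.0),
                              v, "beech_dominated", params = p)
  expect_equal(ec, c(0.15, 0.15 * 1.60))
})

test_that("both multipliers compose and the result is clamped to [0, 1]", {
  p <- default_params()
  v <- management_variant(0, 1.60, 1.60)
  e <- effective_probability(0.2, "spruce", 55, v, "spruce_dominated",
                             params = p)
  expect_equal(e, 0.2 * 0.75 * 1.6 * 1.6)
  expect_equal(
    effective_probability(0.9, "spruce", 55, v, "spruce_dominated", params = p),
    1)  # clamped
})

test_that("small planted trees are exempt from removal", {
  p <- default_params()
  ref <- management_variant(0, 1, 1)
  e <- effective_probability(c(0.2, 0.2), c("douglas_fir", "douglas_fir"),
                             c(18, 25), ref, "spruce_dominated",
                             origin = c("planted", "planted"), params = p)
  expect_equal(e, c(0, 0.15))
})

test_that("harvest removes no trees at probability 0 and all at probability 1", {
  p <- default_params()
  st <- make_stand(seq(15, 60, by = 5))
  p0 <- p; p0$removal$intercept <- -1e9
  out0 <- harvest(st, management_variant(0, 1, 1), baseline_step(), p0)
  expect_equal(nrow(out0$removed), 0)
  p1 <- p; p1$removal$intercept <- 1e9
  v_all <- management_variant(0, 1, 1, reference_reduction = 0, strict = FALSE)
  out1 <- harvest(st, v_all, baseline_step(), p1)
  expect_equal(nrow(out1$removed), nrow(st$trees))
  expect_equal(stand_metrics(out1$stand)$growing_stock, 0)
  expect_true(all(out1$stand$trees$status == "harvested"))
})

test_that("harvest removal fraction matches the binomial oracle", {
  p <- default_params()
  # flat removal model: probability 0.16 for every tree after the reduction
  p$removal[c("dbh", "dbh2", "increment", "ba", "ln_stems", "dt")] <- 0
  p$removal$intercept <- qlogis(0.16 / 0.75)
  st <- make_stand(rep(30, 10000))
  set.seed(13)
  out <- harvest(st, management_variant(0, 1, 1), baseline_step(), p)
  frac <- nrow(out$removed) / 10000
  expect_lt(abs(frac - 0.16), 3 * sqrt(0.16 * 0.84 / 10000))
})

test_that("preparatory thinning follows the stage schedule", {
  # mature 2016: all trees above 30 cm go
  st <- make_stand(c(20, 29, 31, 45, 80), stage = "mature")
  out <- preparatory_thin(st, 2016)
  expect_setequal(out$removed$dbh, c(31, 45, 80))
  expect_equal(sort(live_dbh <- out$stand$trees$dbh[out$stand$trees$status == "live"]),
               c(20, 29))
  # pole 2026: 30% of trees above 20 cm
  st2 <- make_stand(seq(13, 40, length.out = 30), stage = "pole")
  set.seed(1)
  out2 <- preparatory_thin(st2, 2026)
  n_qual <- sum(st2$trees$dbh > 20)
  expect_equal(nrow(out2$removed), round(0.3 * n_qual))
  expect_true(all(out2$removed$dbh > 20))
  # years outside the schedule are a no-op
  out3 <- preparatory_thin(st2, 2041)
  expect_equal(nrow(out3$removed), 0)
  expect_identical(out3$stand$trees, st2$trees)
  # no qualifying trees: unchanged
  st4 <- make_stand(c(13, 14), stage = "mature")
  out4 <- preparatory_thin(st4, 2016)
  expect_equal(nrow(out4$removed), 0)
})

test_that("planting mixes follow largest-remainder rounding exactly", {
  set.seed(2)
  ps <- plant(management_variant(400, 1, 1), "spruce_dominated", id_start = 1)
  counts <- table(ps$species_group)
  expect_equal(unname(counts[c("douglas_fir", "oak", "fir")]),
               c(160L, 160L, 80L), ignore_attr = TRUE)
  pb <- plant(management_variant(300, 1, 1), "beech_dominated", id_start = 1)
  expect_equal(unname(table(pb$species_group)), rep(100L, 3), ignore_attr = TRUE)
  expect_equal(nrow(plant(management_variant(0, 1, 1), "beech_dominated")), 0)
  expect_true(all(ps$origin == "planted"))
  expect_lt(abs(mean(ps$dbh) - 12), 0.2)
})

test_that("management variants restrict levels unless overridden", {
  expect_error(management_variant(150, 1, 1))
  expect_error(management_variant(0, 1.2, 1))
  v <- management_variant(150, 1.2, 1, strict = FALSE)
  expect_equal(v$planting_n, 150)
  expect_true(management_variant(0, 1, 1)$is_reference)
  expect_false(management_variant(100, 1, 1)$is_reference)
})
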