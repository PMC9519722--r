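test_that("Shannon index closed forms", {
  expect_equal(shannon_index(make_stand(c(20, 30, 40), species = "beech")), 0)
  # three species with equal basal area
  st3 <- make_stand(c(30, 30, 30), species = c("beech", "spruce", "oak"))
  expect_equal(shannon_index(st3), log(3))
  st2 <- make_stand(c(25, 25), species = c("fir", "oak"))
  expect_equal(shannon_index(st2), log(2))
  expect_equal(shannon_index(make_stand(numeric(0))), 0)
})

test_that("structural index closed forms and permutation invariance", {
  # single DBH and height class
  st1 <- make_stand(c(21, 22), height = c(10.5, 10.9))
  expect_equal(structural_index(st1), 0)
  # equal basal area in 4 DBH classes x 2 height classes:
  # counts 64/16/4/1 at dbh 5/10/20/40 equalise class basal areas
  dbh <- c(rep(5, 64), rep(10, 16), rep(20, 4), 40)
  height <- c(rep(10.5, 64), rep(20.5, 16), rep(20.5, 4), 10.5)
  st <- make_stand(dbh, height = height)
  expect_equal(structural_index(st), (log(4) + log(2)) / 2)
  perm <- sample(length(dbh))
  stp <- make_stand(dbh[perm], height = height[perm])
  expect_equal(structural_index(stp), structural_index(st))
  expect_equal(shannon_index(stp), shannon_index(st))
})

test_that("habitat trees use a strict 70-cm threshold", {
  st <- make_stand(c(69.9, 70.0, 70.1))
  expect_equal(habitat_trees(st), 1)
  expect_equal(habitat_trees(make_stand(numeric(0))), 0)
  expect_equal(habitat_trees(make_stand(rep(75, 5))), 5)
})

test_that("living carbon applies the 51%/48% leaf-type fractions", {
  p <- default_params()
  for (g in names(p$species)) {
    p$species[[g]]$vol_a <- 1e-4; p$species[[g]]$vol_b <- 2
    p$species[[g]]$wood_density <- 1
  }
  p$carbon$belowground_expansion <- 1
  # dbh 100 -> volume 1 m3 -> biomass 1 t
  expect_equal(carbon_living(make_stand(100, species = "spruce"), p), 0.51)
  expect_equal(carbon_living(make_stand(100, species = "beech"), p), 0.48)
  expect_equal(carbon_living(make_stand(numeric(0)), p), 0)
})

test_that("harvest splits 90/10 into products and residue, conserving volume", {
  s <- split_harvest(100)
  expect_equal(s$product, 90)
  expect_equal(s$residue, 10)
  expect_equal(split_harvest(0)$product, 0)
  v <- c(12.3, 45.6)
  s2 <- split_harvest(v)
  expect_equal(s2$product + s2$residue, v)
})

test_that("deadwood decay matches the analytic exponential", {
  p <- default_params()
  pool <- c(coarse_conifer = 10, fine_conifer = 2,
            coarse_broadleaf = 8, fine_broadleaf = 1)
  # zero rates: unchanged
  p0 <- p; p0$deadwood$k_conifer <- 0; p0$deadwood$k_broadleaf <- 0
  out0 <- decay_deadwood(pool, t_annual = 7.5, dt = 5, params = p0)
  expect_equal(out0$pool, pool)
  # k * dt = ln 2 at the reference temperature: coarse pools halve
  p1 <- p
  p1$deadwood$k_conifer <- log(2) / 5
  p1$deadwood$k_broadleaf <- log(2) / 5
  out1 <- decay_deadwood(pool, t_annual = p1$deadwood$t_ref, dt = 5,
                         params = p1)
  expect_equal(unname(out1$pool["coarse_conifer"]), 5)
  expect_equal(unname(out1$pool["coarse_broadleaf"]), 4)
  # five-times-faster fine decay: remaining fine fraction = coarse^5
  p2 <- default_params()
  pool1 <- c(coarse_conifer = 1, fine_conifer = 1,
             coarse_broadleaf = 1, fine_broadleaf = 1)
  out2 <- decay_deadwood(pool1, t_annual = 12, dt = 7, params = p2)
  expect_equal(unname(out2$pool["fine_conifer"]),
               unname(out2$pool["coarse_conifer"])^5)
  expect_equal(unname(out2$pool["fine_broadleaf"]),
               unname(out2$pool["coarse_broadleaf"])^5)
  # Q10 temperature sensitivity: warmer means faster decay
  warm <- decay_deadwood(pool1, t_annual = 17, dt = 5, params = p2)
  cold <- decay_deadwood(pool1, t_annual = 2, dt = 5, params = p2)
  expect_true(all(warm$pool < cold$pool))
})

test_that("deadwood and HWP ledgers close exactly", {
  p <- default_params()
  pool <- c(coarse_conifer = 10, fine_conifer = 2,
            coarse_broadleaf = 8, fine_broadleaf = 1)
  input <- c(coarse_conifer = 3, fine_conifer = 1,
             coarse_broadleaf = 2, fine_broadleaf = 0.5)
  out <- decay_deadwood(pool, input, t_annual = 9, dt = 5, params = p)
  expect_equal(out$pool + out$decayed, pool + input, tolerance = 1e-12)

  pools <- c(sawn_timber = 5, panels = 2, paper = 0.5, energy = 0.1)
  hw <- update_hwp(pools, c(conifer = 40, broadleaf = 25), dt = 5, params = p)
  expect_equal(unname(sum(hw$pools) + sum(hw$decayed)),
               unname(sum(pools) + sum(hw$inflow)), tolerance = 1e-9)
})

test_that("HWP pools respect allocation and limiting decay rates", {
  p <- default_params()
  # zero inflow, infinite half-lives: unchanged
  p0 <- p; p0$hwp$half_life[] <- Inf
  pools <- c(sawn_timber = 5, panels = 2, paper = 0.5, energy = 0.1)
  expect_equal(update_hwp(pools, c(conifer = 0, broadleaf = 0), 5, p0)$pools,
               pools)
  # all inflow to energy wood with a near-zero half-life vanishes in a step
  p1 <- p
  p1$hwp$alloc_conifer <- c(sawn_timber = 0, panels = 0, paper = 0, energy = 1)
  p1$hwp$half_life["energy"] <- 1e-6
  out <- update_hwp(c(sawn_timber = 0, panels = 0, paper = 0, energy = 0),
                    c(conifer = 100, broadleaf = 0), dt = 5, params = p1)
  expect_lt(unname(out$pools["energy"]), 1e-12)
  expect_gt(unname(out$inflow["energy"]), 0)
})

test_that("the ESB record assembles all ten indicators per step", {
  p <- default_params()
  st <- example_stand()
  rec <- esb_record(st, harvested_volume = 0, increment_volume = 0, params = p)
  expect_equal(rec$harvested_volume, 0)
  expect_equal(rec$volume_increment, 0)
  expect_equal(rec$deadwood_volume, sum(st$deadwood))
  expect_equal(rec$carbon_hwp, sum(st$hwp))
  need <- c("growing_stock", "harvested_volume", "volume_increment",
            "carbon_living", "carbon_deadwood", "carbon_hwp", "shannon",
            "structural", "deadwood_volume", "habitat_trees")
  expect_true(all(need %in% names(rec)))
  expect_lte(rec$shannon, log(length(unique(st$trees$species_group))))
})
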