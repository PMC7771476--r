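test_that("surplus levels match their linearized closed forms", {
  # demand triangle: intercept 300, area 0.5 * 200 * 50
  expect_equal(consumer_surplus(price = 100, quantity = 50,
                                elasticity = -0.5), 5000)
  expect_error(consumer_surplus(100, 50, 0.5), "negative")
  # elastic supply triangle: price intercept 50
  expect_equal(producer_surplus(100, 50, eps_s = 2), 1250)
  # inelastic supply: trapezoid truncated at price zero
  expect_equal(producer_surplus(100, 50, eps_s = 0.5), 3750)
  # branch continuity at unit elasticity
  expect_equal(producer_surplus(100, 50, eps_s = 1), 2500)
  expect_equal(producer_surplus(100, 50, eps_s = 1 - 1e-12),
               producer_surplus(100, 50, eps_s = 1 + 1e-12),
               tolerance = 1e-9)
  # linear in quantity, vanishing under perfectly elastic demand
  expect_equal(consumer_surplus(100, 25, -0.5),
               consumer_surplus(100, 50, -0.5) / 2)
  expect_lt(consumer_surplus(100, 50, -1e6), 1e-2)
})

test_that("the closed-form surplus oracle evaluates the textbook formulas", {
  out <- alston_surplus(k = 0.1, p0 = 20, q0 = 50, eta = 0.5, eps_s = 1)
  # P0 Q0 = 1000; Z = 0.1/1.5
  z <- 0.1 / 1.5
  expect_equal(out$dcs, 1000 * z * (1 + 0.5 * z * 0.5), tolerance = 1e-12)
  expect_equal(out$dcs, 67.78, tolerance = 1e-3)
  expect_equal(out$dps, 33.89, tolerance = 1e-3)
  expect_equal(out$dtotal, 101.67, tolerance = 1e-3)
  # zero shift, zero change
  zero <- alston_surplus(0, 20, 50, 0.5, 1)
  expect_equal(zero$dtotal, 0)
  # near-vertical demand: all gains accrue to consumers
  tiny <- alston_surplus(0.05, 20, 50, eta = 1e-9, eps_s = 1)
  expect_equal(tiny$dcs / 1000, 0.05, tolerance = 1e-6)
  expect_equal(tiny$dps, 0, tolerance = 1e-6)
  expect_error(alston_surplus(0.9, 20, 50, 0.5, 1), "safeguard")
})

test_that("npv, irr and mirr reproduce hand-computed cases", {
  expect_equal(npv(c(-100, 60, 60), 0.10), -100 + 60 / 1.1 + 60 / 1.21,
               tolerance = 1e-12)
  expect_equal(npv(c(-100, 60, 60), 0.10), 4.1322, tolerance = 1e-4)
  expect_equal(npv(c(1, 2, 3), 0), 6)
  expect_equal(npv(numeric(26), 0.1), 0)

  expect_equal(irr(c(-100, 110)), 0.10, tolerance = 1e-10)
  expect_equal(irr(c(-100, 0, 121)), 0.10, tolerance = 1e-10)
  expect_error(irr(c(100, 110)), "sign change")

  expect_equal(mirr(c(-100, 50, 60), 0.10, 0.10), sqrt(1.15) - 1,
               tolerance = 1e-12)
  expect_equal(mirr(c(-100, 50, 60), 0.10, 0.10), 0.07238, tolerance = 1e-4)
  expect_equal(mirr(c(-100, 110), 0.10, 0.10), 0.10, tolerance = 1e-12)
  # scale invariance
  expect_equal(mirr(c(-100, 50, 60)), mirr(2 * c(-100, 50, 60)),
               tolerance = 1e-12)
  expect_error(mirr(c(10, 20)), "MIRR undefined")
})

test_that("npv is zero at the internal rate of return", {
  withr::with_seed(3, {
    for (i in 1:20) {
      stream <- c(-runif(3, 10, 100), runif(8, 0, 60))
      r <- irr(stream)
      expect_lt(abs(npv(stream, r)), 1e-8)
    }
  })
})

test_that("npv decreases in the rate for investment-shaped streams", {
  stream <- c(-50, -20, 10, 30, 40, 40)
  rates <- seq(0, 0.5, by = 0.05)
  vals <- sapply(rates, function(r) npv(stream, r))
  expect_true(all(diff(vals) < 0))
})

test_that("closed-economy welfare matches the surplus oracle within 2%", {
  withr::with_seed(20, {
    for (i in 1:60) {
      eta <- runif(1, 0.3, 0.8)
      eps_s <- runif(1, 0.3, 0.8)
      k <- runif(1, 0.005, 0.05)
      w <- one_region_world(eta = eta, eps_s = eps_s)
      d <- generate_drivers("static", w)
      sh <- constant_shock(w, "R01", multiplier = (1 - k)^(-eps_s))
      b <- run_scenario(w, d)
      s <- run_scenario(w, d, sh)
      wc <- welfare_change(b, s, w, sh)
      sim <- dplyr::filter(wc, group == "all", year == 2015)
      oracle <- alston_surplus(k, p0 = 200, q0 = 15000, eta = eta,
                               eps_s = eps_s)
      # welfare_change reports million US$ (price x kt / 1000)
      expect_equal(sim$dcs * 1000, oracle$dcs, tolerance = 0.02)
      expect_equal(sim$dps * 1000, oracle$dps, tolerance = 0.02)
    }
  })
})

test_that("welfare changes vanish when the trajectories coincide", {
  w <- two_region_world()
  d <- generate_drivers("static", w)
  b <- run_scenario(w, d)
  sh <- constant_shock(w, "R01", multiplier = 1)
  wc <- welfare_change(b, b, w, sh)
  expect_true(all(wc$dcs == 0))
  expect_true(all(wc$dps == 0))
})

test_that("welfare groups are additive and directionally correct", {
  w <- generate_world(generator_config(n_regions = 8), seed = 5)
  d <- generate_drivers("static", w, seed = 5)
  techs <- potato_technologies(w, seed = 5)
  sh <- build_shock(techs$late_blight_resistance, w, d)
  b <- run_scenario(w, d)
  s <- run_scenario(w, d, sh)
  wc <- welfare_change(b, s, w, sh)
  wide <- tidyr::pivot_wider(wc, names_from = group,
                             values_from = c(dcs, dps))
  expect_equal(wide$dcs_all, wide$dcs_target + wide$dcs_non_target,
               tolerance = 1e-10)
  expect_equal(wide$dps_all, wide$dps_target + wide$dps_non_target,
               tolerance = 1e-10)
  post <- wide[wide$year > sh$release_year, ]
  # consumers gain everywhere; non-target producers face the lower world
  # price without the yield gain
  expect_true(all(post$dcs_all > 0))
  expect_true(all(post$dps_non_target < 0))
  expect_true(all(post$dps_target > 0))
})

test_that("mismatched horizons are rejected", {
  w <- two_region_world()
  d <- generate_drivers("static", w)
  b <- run_scenario(w, d)
  w2 <- two_region_world(horizon = c(2015L, 2020L))
  b2 <- run_scenario(w2, generate_drivers("static", w2))
  sh <- constant_shock(w, "R01", 1.01)
  expect_error(welfare_change(b, b2, w, sh), "different horizons")
})

test_that("technology ranking orders by metric with alphabetical ties", {
  reports <- tibble::tibble(
    technology = c("b_tech", "a_tech", "c_tech"),
    aggregation = "all",
    net_npv = c(5, 5, 10), irr = c(0.1, 0.2, 0.3), mirr = c(0.1, 0.2, 0.3))
  r <- rank_technologies(reports, "npv")
  expect_equal(r$technology, c("c_tech", "a_tech", "b_tech"))
  expect_equal(r$rank, 1:3)
  single <- rank_technologies(reports[1, ], "npv")
  expect_equal(nrow(single), 1)
  expect_error(rank_technologies(dplyr::select(reports, -net_npv), "npv"),
               "missing")
})
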