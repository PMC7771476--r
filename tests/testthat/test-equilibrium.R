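test_that("yield response reproduces its calibration point and power law", {
  w <- two_region_world()
  d <- generate_drivers("static", w)
  y0 <- compute_yield(w, d, "R01", "potato", 2015, price = 250)
  expect_equal(y0, 10, tolerance = 1e-12)
  # own-price response: eps = 0.2, price doubled
  y2 <- compute_yield(w, d, "R01", "potato", 2015, price = 500)
  expect_equal(y2, 10 * 2^0.2, tolerance = 1e-12)
  expect_error(compute_yield(w, d, "R01", "potato", 2015, price = -1),
               "positive")
})

test_that("climate multipliers scale yields directly", {
  w <- two_region_world()
  d <- generate_drivers("static", w)
  d$yield_paths$yclim <- 0.95
  expect_equal(compute_yield(w, d, "R02", "potato", 2020, price = 250),
               0.95 * 20, tolerance = 1e-12)
})

test_that("area and demand responses are constant-elasticity at the base point", {
  w <- generate_world(generator_config(n_regions = 3), seed = 4)
  d <- generate_drivers("static", w)
  p0 <- w$calibration |>
    dplyr::distinct(commodity, price_base)
  prices <- stats::setNames(p0$price_base, p0$commodity)
  cal <- w$calibration[1, ]
  expect_equal(compute_area(w, cal$region, cal$commodity, 2015, prices),
               cal$area_base, tolerance = 1e-12)
  expect_equal(compute_demand(w, d, cal$region, cal$commodity, 2015, prices),
               cal$demand_base, tolerance = 1e-12)
  # own-price area response
  own <- w$area_elasticity |>
    dplyr::filter(region == cal$region, commodity == cal$commodity,
                  wrt == cal$commodity)
  p_up <- prices
  p_up[cal$commodity] <- p_up[cal$commodity] * 1.1
  expect_equal(compute_area(w, cal$region, cal$commodity, 2015, p_up) /
                 cal$area_base,
               1.1^own$elast *
                 prod((p_up / prices)[setdiff(names(prices), cal$commodity)]^
                        (w$area_elasticity |>
                           dplyr::filter(region == cal$region,
                                         commodity == cal$commodity,
                                         wrt != cal$commodity) |>
                           dplyr::arrange(match(wrt, setdiff(names(prices), cal$commodity))) |>
                           dplyr::pull(elast))),
               tolerance = 1e-10)
  # population scales demand proportionally
  d2 <- d
  d2$demographics$pop_mult <- 1.02
  cal_i <- w$calibration |>
    dplyr::filter(income_elast > 0) |> dplyr::slice(1)
  expect_equal(compute_demand(w, d2, cal_i$region, cal_i$commodity, 2015, prices) /
                 compute_demand(w, d, cal_i$region, cal_i$commodity, 2015, prices),
               1.02, tolerance = 1e-12)
})

test_that("excess demand vanishes at the calibration point and responds to shocks", {
  w <- generate_world(generator_config(n_regions = 4), seed = 6)
  d <- generate_drivers("static", w)
  p0 <- w$calibration |> dplyr::distinct(commodity, price_base)
  prices <- stats::setNames(p0$price_base, p0$commodity)
  r0 <- excess_demand(w, d, 2015, prices)
  expect_true(all(abs(r0) < 1e-6))
  # a positive focus-crop yield shock creates excess supply at base prices
  sh <- constant_shock(w, w$regions$region[1], multiplier = 1.05)
  r1 <- excess_demand(w, d, 2015, prices, shock = sh)
  expect_lt(r1[["potato"]], 0)
})

test_that("the solved base year returns base prices", {
  w <- generate_world(generator_config(n_regions = 4), seed = 8)
  d <- generate_drivers("static", w)
  sol <- solve_year(w, d, 2015)
  p0 <- w$calibration |> dplyr::distinct(commodity, price_base)
  expect_equal(unname(sol$prices[p0$commodity]), p0$price_base,
               tolerance = 1e-10)
})

test_that("a one-market world matches the algebraic log-linear solution", {
  eta <- 0.5
  eps_s <- 0.4
  shift <- 0.04
  w <- one_region_world(eta = eta, eps_s = eps_s)
  d <- generate_drivers("static", w)
  sh <- constant_shock(w, "R01", multiplier = 1 + shift)
  sol <- solve_year(w, d, 2015, shock = sh)
  p_star <- 200 * (1 + shift)^(1 / (-eta - eps_s))
  expect_equal(sol$prices[["potato"]], p_star, tolerance = 1e-6)
  # quantities lie on the demand curve at the solved price
  q_star <- 15000 * (p_star / 200)^(-eta)
  expect_equal(sol$slice$demand, q_star, tolerance = 1e-6)
  expect_equal(sol$slice$supply, q_star, tolerance = 1e-6)
})

test_that("solved trajectories clear every market in every year", {
  w <- generate_world(generator_config(n_regions = 12), seed = 1)
  d <- generate_drivers("SSP2-RCP6.0", w, seed = 1)
  techs <- potato_technologies(w, seed = 1)
  sh <- build_shock(techs$late_blight_resistance, w, d)
  tr <- run_scenario(w, d, sh)
  nt <- tr |>
    dplyr::group_by(year, commodity) |>
    dplyr::summarise(nt = sum(net_trade), base = sum(demand), .groups = "drop")
  expect_true(all(abs(nt$nt / nt$base) <= 1e-7))
  expect_true(all(tr$supply > 0 & tr$demand > 0 & tr$world_price > 0))
  expect_equal(tr$supply, tr$yield * tr$area, tolerance = 1e-12)
})

test_that("a static no-shock run repeats the base year exactly", {
  w <- generate_world(generator_config(n_regions = 5), seed = 10)
  d <- generate_drivers("static", w, seed = 10)
  tr <- run_scenario(w, d)
  years <- unique(tr$year)
  first <- dplyr::filter(tr, year == years[1]) |> dplyr::select(-year)
  for (yr in years[-1]) {
    expect_identical(dplyr::filter(tr, year == yr) |> dplyr::select(-year),
                     first)
  }
})

test_that("a null technology shock reproduces the baseline bit-for-bit", {
  w <- generate_world(generator_config(n_regions = 5), seed = 12)
  d <- generate_drivers("SSP1-RCP4.5", w, seed = 12)
  baseline <- run_scenario(w, d)
  tech0 <- technology_option("null", 2, 10, 1, 50,
                             tibble::tibble(region = w$regions$region[w$regions$target][1],
                                            amax = 0.4, dy = 0.3, dc = 0, p = 0))
  shocked <- run_scenario(w, d, build_shock(tech0, w, d))
  expect_identical(tidy(shocked), tidy(baseline))
})

test_that("a positive focus-crop shock lowers the world focus price", {
  w <- generate_world(generator_config(n_regions = 6), seed = 14)
  d <- generate_drivers("static", w, seed = 14)
  techs <- potato_technologies(w, seed = 14)
  b <- run_scenario(w, d)
  s <- run_scenario(w, d, build_shock(techs$virus_resistance, w, d))
  pb <- dplyr::filter(b, commodity == "potato", year == 2040)$world_price[1]
  ps <- dplyr::filter(s, commodity == "potato", year == 2040)$world_price[1]
  expect_lt(ps, pb)
})

test_that("demand under high-population drivers exceeds the sustainable path", {
  w <- generate_world(generator_config(n_regions = 4), seed = 15)
  d1 <- generate_drivers("SSP1-RCP4.5", w, seed = 15)
  d3 <- generate_drivers("SSP3-RCP8.5", w, seed = 15)
  p0 <- w$calibration |> dplyr::distinct(commodity, price_base)
  prices <- stats::setNames(p0$price_base, p0$commodity)
  # at constant prices, focus-crop demand is strictly higher under SSP3
  d_ssp1 <- sum(sapply(w$regions$region, function(r)
    compute_demand(w, d1, r, "potato", 2040, prices)))
  d_ssp3 <- sum(sapply(w$regions$region, function(r)
    compute_demand(w, d3, r, "potato", 2040, prices)))
  expect_gt(d_ssp3, d_ssp1)
})
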