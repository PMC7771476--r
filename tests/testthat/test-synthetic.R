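test_that("world generation is deterministic in the seed", {
  cfg <- generator_config(n_regions = 5)
  w1 <- generate_world(cfg, seed = 42)
  w2 <- generate_world(cfg, seed = 42)
  expect_identical(w1, w2)
  w3 <- generate_world(cfg, seed = 43)
  expect_false(identical(w1$calibration, w3$calibration))
})

test_that("generated worlds have the requested structure", {
  w <- generate_world(generator_config(n_regions = 12), seed = 3)
  expect_equal(nrow(w$regions), 12)
  expect_equal(nrow(w$commodities), 3)
  clearing <- w$calibration |>
    dplyr::group_by(commodity) |>
    dplyr::summarise(resid = sum(yield_base * area_base) - sum(demand_base))
  expect_true(all(abs(clearing$resid) < 1e-8 * 1e5))
  # at least one non-target region produces the focus crop
  nt <- w$regions$region[!w$regions$target]
  focus_rows <- dplyr::filter(w$calibration, commodity == "potato",
                              region %in% nt)
  expect_gt(nrow(focus_rows), 0)
  expect_true(all(focus_rows$area_base > 0))
})

test_that("the focus crop holds its configured share of production value", {
  share <- 0.15
  w <- generate_world(generator_config(focus_value_share = share), seed = 9)
  value <- w$calibration |>
    dplyr::group_by(commodity) |>
    dplyr::summarise(v = sum(price_base * yield_base * area_base))
  got <- value$v[value$commodity == "potato"] / sum(value$v)
  expect_equal(got, share, tolerance = 1e-10)
})

test_that("infeasible generator configurations are rejected", {
  expect_error(generator_config(n_regions = 1), "n_regions")
  expect_error(generator_config(target_share = 1.2), "target_share")
  expect_error(generate_world(list(), seed = 1), "generator_config")
})

test_that("static drivers freeze every path at its base value", {
  w <- two_region_world()
  d <- generate_drivers("static", w, seed = 5)
  expect_true(all(d$demographics$pop_mult == 1))
  expect_true(all(d$demographics$income_mult == 1))
  expect_true(all(d$yield_paths$yint2 == 1))
  expect_true(all(d$yield_paths$yclim == 1))
  expect_equal(d$adoption_ceiling_factor, 1.0)
})

test_that("adoption ceilings shift by socioeconomic pathway", {
  w <- two_region_world()
  expect_equal(generate_drivers("SSP1-RCP4.5", w)$adoption_ceiling_factor, 1.10)
  expect_equal(generate_drivers("SSP2-RCP6.0", w)$adoption_ceiling_factor, 1.00)
  expect_equal(generate_drivers("SSP3-RCP8.5", w)$adoption_ceiling_factor, 0.90)
})

test_that("unknown pathway names are rejected", {
  expect_error(generate_drivers("SSP4-RCP2.6", two_region_world()),
               "unknown pathway")
})

test_that("driver orderings across pathways hold for every region and seed", {
  w <- generate_world(generator_config(n_regions = 6), seed = 2)
  final <- function(d) {
    dplyr::filter(d$demographics, year == max(year))
  }
  for (seed in c(1, 13, 77)) {
    d1 <- generate_drivers("SSP1-RCP4.5", w, seed = seed)
    d2 <- generate_drivers("SSP2-RCP6.0", w, seed = seed)
    d3 <- generate_drivers("SSP3-RCP8.5", w, seed = seed)
    # population growth: SSP3 > SSP2 > SSP1 in every region
    expect_true(all(final(d3)$pop_mult > final(d2)$pop_mult))
    expect_true(all(final(d2)$pop_mult > final(d1)$pop_mult))
    # income growth ordered the other way
    expect_true(all(final(d1)$income_mult > final(d2)$income_mult))
    expect_true(all(final(d2)$income_mult > final(d3)$income_mult))
    # climate severity: RCP4.5 mildest, RCP8.5 harshest, beyond the base year
    yc <- function(d) dplyr::filter(d$yield_paths, year > min(year))$yclim
    expect_true(all(yc(d1) > yc(d2)))
    expect_true(all(yc(d2) > yc(d3)))
  }
})

test_that("technology fixtures carry the published cost and lag structure", {
  w <- generate_world(seed = 1)
  techs <- potato_technologies(w, seed = 1)
  expect_named(techs, c("improved_seed_systems", "bacterial_wilt_resistance",
                        "virus_resistance", "late_blight_resistance"))

  seed_sys <- techs$improved_seed_systems
  expect_equal(seed_sys$research_lag, 3L)
  expect_equal(seed_sys$adoption_lag, 5L)
  expect_equal(seed_sys$annual_rd_cost, 8)
  expect_equal(seed_sys$dissemination_cost_per_ha, 80)
  expect_true(all(seed_sys$targets$amax >= 0.03 & seed_sys$targets$amax <= 0.20))
  expect_true(all(seed_sys$targets$dy == 0.20))
  expect_true(all(seed_sys$targets$dc == 0.20))
  expect_true(all(seed_sys$targets$p >= 0.6 & seed_sys$targets$p <= 0.8))

  wilt <- techs$bacterial_wilt_resistance
  expect_equal(wilt$research_lag, 10L)
  expect_equal(wilt$adoption_lag, 10L)
  expect_equal(wilt$annual_rd_cost, 4)
  expect_equal(wilt$dissemination_cost_per_ha, 50)
  expect_true(all(wilt$targets$p == 0.5))
  expect_true(all(wilt$targets$dy >= 0.10 & wilt$targets$dy <= 0.30))
  expect_true(all(wilt$targets$dc == 0))

  virus <- techs$virus_resistance
  expect_equal(virus$research_lag, 2L)
  expect_equal(virus$annual_rd_cost, 8)
  expect_true(all(virus$targets$dy == 0.40))
  expect_true(all(virus$targets$dc == -0.05))
  expect_true(all(virus$targets$p == 0.7))
  expect_true(all(virus$targets$amax >= 0.15 & virus$targets$amax <= 0.40))

  blight <- techs$late_blight_resistance
  expect_equal(blight$research_lag, 2L)
  expect_equal(blight$adoption_lag, 10L)
  expect_equal(blight$annual_rd_cost, 16)
  expect_equal(blight$dissemination_cost_per_ha, 50)
  expect_true(all(blight$targets$p == 0.8))
  expect_true(all(blight$targets$dy >= 0.12 & blight$targets$dy <= 0.32))
  expect_true(all(blight$targets$dc >= -0.05 & blight$targets$dc <= -0.02))
})

test_that("technology constructor enforces parameter ranges", {
  tg <- tibble::tibble(region = "R01", amax = 0.5, dy = 0.2, dc = 0, p = 0.5)
  expect_error(technology_option("x", 1, 1, 1, 1, tg[0, ]), "non-empty")
  tg$amax <- 1.5
  expect_error(technology_option("x", 1, 1, 1, 1, tg), "amax")
  tg$amax <- 0.5; tg$p <- 1.2
  expect_error(technology_option("x", 1, 1, 1, 1, tg), "p must")
})
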