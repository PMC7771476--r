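# Hand-built fixture worlds used across the test files.

# Two-region, one-commodity world with explicit numbers (region R02 is the
# non-target exporter).
two_region_world <- function(horizon = c(2015L, 2040L)) {
  cal <- tibble::tibble(
    region = c("R01", "R02"), commodity = "potato",
    yield_base = c(10, 20), area_base = c(200, 800),
    price_base = 250, demand_base = c(3000, 15000),
    yield_price_elast = c(0.2, 0.1), input_price_elast = -0.1,
    input_price_base = 1, income_elast = c(0.4, 0.3))
  world_model(
    commodities = tibble::tibble(commodity = "potato", is_focus = TRUE),
    regions = tibble::tibble(region = c("R01", "R02"),
                             target = c(TRUE, FALSE)),
    calibration = cal,
    demographics = tibble::tibble(region = c("R01", "R02"),
                                  population = c(40, 120), income = 1),
    area_elasticity = tibble::tibble(region = c("R01", "R02"),
                                     commodity = "potato", wrt = "potato",
                                     elast = c(0.3, 0.2)),
    demand_elasticity = tibble::tibble(region = c("R01", "R02"),
                                       commodity = "potato", wrt = "potato",
                                       elast = c(-0.5, -0.4)),
    horizon = horizon)
}

# The seeded 12-region fixture study used by the qualitative reproduction
# tests; built once per test run.
fixture_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      world <- generate_world(generator_config(), seed = 1)
      techs <- potato_technologies(world, seed = 1)
      cache <<- run_priority_study(world, techs,
                                   pathways = ssp_rcp_pathways(), seed = 1)
    }
    cache
  }
})
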