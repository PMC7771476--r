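#' Generator configuration for synthetic worlds
#'
#' The generator emulates the calibration a global agricultural-sector model
#' would take from FAOSTAT-like statistics: per-region base harvested areas,
#' yields, producer prices and food demand for a focus root crop plus two
#' related cereal staples, together with demand, income, yield and area
#' price-elasticities drawn from documented ranges. Magnitudes are chosen so
#' the focus crop is a comparatively small sector (15% of the three-crop
#' production value by default) and so that target regions are small
#' producers, net importers of the focus crop, with at most one large
#' producer among them.
#'
#' @param n_regions Number of regions (>= 2; default 12).
#' @param commodities Commodity ids; first entry is the focus crop.
#' @param target_share Fraction of regions flagged as technology targets.
#' @param focus_value_share Share of the focus crop in total base-year
#'   production value across all commodities (enforced exactly by scaling the
#'   non-focus sectors).
#' @param horizon Simulation years `c(first, last)`.
#' @param elasticities Named list of `c(lo, hi)` ranges: `demand_own`
#'   (negative), `demand_cross`, `income`, `yield_price`, `area_own`,
#'   `area_cross`, `input_price`.
#' @param magnitudes Named list of `c(lo, hi)` ranges for base magnitudes
#'   (areas in kha, yields in t/ha, prices in US$/t, population in millions).
#' @param import_tilt Demand/supply ratio targets used before the clearing
#'   rescale: scalar for target regions (net importers of the focus crop) and
#'   a range for non-target regions (net exporters).
#' @return A list of class `pe_genconfig`.
#' @export
generator_config <- function(n_regions = 12L,
                             commodities = c("potato", "rice", "wheat"),
                             target_share = 0.5,
                             focus_value_share = 0.15,
                             horizon = c(2015L, 2040L),
                             elasticities = list(
                               demand_own = c(-0.8, -0.2),
                               demand_cross = c(0, 0.1),
                               income = c(0.1, 0.7),
                               yield_price = c(0.05, 0.3),
                               area_own = c(0.1, 0.5),
                               area_cross = c(-0.1, 0),
                               input_price = c(-0.3, -0.05)
                             ),
                             magnitudes = list(
                               focus_yield = c(10, 25),
                               other_yield = c(2.5, 6),
                               focus_price = c(150, 350),
                               other_price = c(150, 450),
                               area_nontarget = c(800, 4000),
                               area_target_small = c(80, 500),
                               area_target_large = c(700, 1200),
                               area_other = c(2000, 20000),
                               population = c(10, 300)
                             ),
                             import_tilt = list(target = 1.35,
                                                nontarget = c(0.80, 0.95))) {
  if (n_regions < 2) {
    rlang::abort("generator config infeasible: n_regions must be >= 2")
  }
  if (length(commodities) < 1 || anyDuplicated(commodities)) {
    rlang::abort("generator config infeasible: commodities must be unique")
  }
  if (target_share <= 0 || target_share >= 1) {
    rlang::abort("generator config infeasible: target_share must be in (0, 1)")
  }
  ranges <- c(elasticities, magnitudes)
  ok <- vapply(ranges, function(r) length(r) == 2 && r[1] <= r[2], logical(1))
  if (!all(ok)) {
    rlang::abort(sprintf("generator config infeasible: range(s) not ordered: %s",
                         paste(names(ranges)[!ok], collapse = ", ")))
  }
  structure(
    list(n_regions = as.integer(n_regions), commodities = commodities,
         focus = commodities[1], target_share = target_share,
         focus_value_share = focus_value_share, horizon = as.integer(horizon),
         elasticities = elasticities, magnitudes = magnitudes,
         import_tilt = import_tilt),
    class = "pe_genconfig")
}

runif_range <- function(n, range) stats::runif(n, range[1], range[2])

#' Generate a synthetic world model
#'
#' Draws a complete, internally consistent market calibration from the ranges
#' in a [generator_config()]. Base-year clearing holds exactly: demands are
#' tilted so target regions are net importers of the focus crop, then rescaled
#' per commodity so global demand equals global supply. The same seed always
#' produces an identical world; [validate_world()] on the result is empty for
#' any seed.
#'
#' @param config A `pe_genconfig`.
#' @param seed Integer seed controlling all draws.
#' @return A `pe_world`.
#' @export
generate_world <- function(config = generator_config(), seed = 1L) {
  if (!inherits(config, "pe_genconfig")) {
    rlang::abort("config must be created by generator_config()")
  }
  n <- config$n_regions
  cms <- config$commodities
  focus <- config$focus
  mg <- config$magnitudes
  el <- config$elasticities

  withr::with_seed(seed, {
    region_ids <- sprintf("R%02d", seq_len(n))
    n_target <- min(max(1L, as.integer(round(config$target_share * n))), n - 1L)
    target_ids <- sort(sample(region_ids, n_target))
    is_target <- region_ids %in% target_ids

    # focus-crop areas: non-targets are large producers; targets small,
    # except one larger producer among the targets
    area_focus <- numeric(n)
    area_focus[!is_target] <- runif_range(sum(!is_target), mg$area_nontarget)
    area_focus[is_target] <- runif_range(n_target, mg$area_target_small)
    big_target <- sample(which(is_target), 1L)
    area_focus[big_target] <- runif_range(1L, mg$area_target_large)

    grid <- tidyr::expand_grid(region = region_ids, commodity = cms)
    n_rc <- nrow(grid)

    area <- numeric(n_rc)
    yield <- numeric(n_rc)
    idx_focus <- grid$commodity == focus
    area[idx_focus] <- area_focus[match(grid$region[idx_focus], region_ids)]
    area[!idx_focus] <- runif_range(sum(!idx_focus), mg$area_other)
    yield[idx_focus] <- runif_range(sum(idx_focus), mg$focus_yield)
    yield[!idx_focus] <- runif_range(sum(!idx_focus), mg$other_yield)

    # one world base price per commodity (domestic price = world price)
    price_by_cm <- stats::setNames(
      c(runif_range(1L, mg$focus_price),
        runif_range(length(cms) - 1L, mg$other_price)), cms)
    price <- price_by_cm[grid$commodity]

    supply <- yield * area
    tilt <- numeric(n_rc)
    row_target <- is_target[match(grid$region, region_ids)]
    tilt[idx_focus & row_target] <- config$import_tilt$target
    tilt[idx_focus & !row_target] <-
      runif_range(sum(idx_focus & !row_target), config$import_tilt$nontarget)
    tilt[!idx_focus] <- stats::runif(sum(!idx_focus), 0.8, 1.2)
    demand_raw <- supply * tilt

    # exact base-year clearing per commodity
    demand <- demand_raw
    for (cm in cms) {
      i <- grid$commodity == cm
      demand[i] <- demand_raw[i] * sum(supply[i]) / sum(demand_raw[i])
    }

    # scale the non-focus sectors so the focus crop holds its configured
    # share of total production value
    value <- price * supply
    v_focus <- sum(value[idx_focus])
    v_other <- sum(value[!idx_focus])
    if (length(cms) > 1) {
      lambda <- v_focus * (1 - config$focus_value_share) /
        (config$focus_value_share * v_other)
      area[!idx_focus] <- area[!idx_focus] * lambda
      demand[!idx_focus] <- demand[!idx_focus] * lambda
    }

    calibration <- tibble::tibble(
      region = grid$region, commodity = grid$commodity,
      yield_base = yield, area_base = area,
      price_base = unname(price), demand_base = demand,
      yield_price_elast = runif_range(n_rc, el$yield_price),
      input_price_elast = runif_range(n_rc, el$input_price),
      input_price_base = 1,
      income_elast = runif_range(n_rc, el$income))

    cross <- tidyr::expand_grid(region = region_ids, commodity = cms, wrt = cms)
    own <- cross$commodity == cross$wrt
    demand_el <- cross
    demand_el$elast <- ifelse(own,
                              runif_range(nrow(cross), el$demand_own),
                              runif_range(nrow(cross), el$demand_cross))
    area_el <- cross
    area_el$elast <- ifelse(own,
                            runif_range(nrow(cross), el$area_own),
                            runif_range(nrow(cross), el$area_cross))

    demographics <- tibble::tibble(
      region = region_ids,
      population = runif_range(n, mg$population),
      income = 1)

    world_model(
      commodities = tibble::tibble(commodity = cms, is_focus = cms == focus),
      regions = tibble::tibble(region = region_ids, target = is_target),
      calibration = calibration,
      demographics = demographics,
      area_elasticity = area_el,
      demand_elasticity = demand_el,
      horizon = config$horizon)
  })
}

#' Closed one-region, one-commodity world
#'
#' A minimal calibrated economy used for verification against closed-form
#' results: a single region producing and consuming the focus crop, with the
#' demand elasticity magnitude `eta` and the supply elasticity `eps_s` split
#' evenly between the yield and area price responses.
#'
#' @param eta Own-price demand elasticity magnitude (positive).
#' @param eps_s Supply price elasticity (positive).
#' @param p0 Base price (US$/t).
#' @param yld Base yield (t/ha).
#' @param area Base harvested area (kha).
#' @param horizon Simulation years.
#' @param target Whether the single region is flagged as a technology
#'   target.
#' @return A `pe_world`.
#' @export
one_region_world <- function(eta = 0.5, eps_s = 0.5, p0 = 200, yld = 15,
                             area = 1000, horizon = c(2015L, 2016L),
                             target = TRUE) {
  world_model(
    commodities = tibble::tibble(commodity = "potato", is_focus = TRUE),
    regions = tibble::tibble(region = "R01", target = target),
    calibration = tibble::tibble(
      region = "R01", commodity = "potato", yield_base = yld,
      area_base = area, price_base = p0, demand_base = yld * area,
      yield_price_elast = eps_s / 2, input_price_elast = -0.1,
      input_price_base = 1, income_elast = 0.3),
    demographics = tibble::tibble(region = "R01", population = 50, income = 1),
    area_elasticity = tibble::tibble(region = "R01", commodity = "potato",
                                     wrt = "potato", elast = eps_s / 2),
    demand_elasticity = tibble::tibble(region = "R01", commodity = "potato",
                                       wrt = "potato", elast = -eta),
    horizon = horizon)
}

#' Recognized scenario pathway names
#'
#' The static counterfactual plus the three SSP-RCP combinations of matched
#' (medium) mitigation cost used in the study design.
#'
#' @return Character vector of pathway names.
#' @export
ssp_rcp_pathways <- function() {
  c("static", "SSP1-RCP4.5", "SSP2-RCP6.0", "SSP3-RCP8.5")
}

# per-SSP annual growth-rate ranges and per-RCP 2040 climate-multiplier
# endpoints; a common per-region uniform draw is mapped into each pathway's
# range, so growth orderings across pathways hold region-by-region for any
# seed
driver_ranges <- function() {
  list(
    pop = list(SSP1 = c(0.002, 0.008), SSP2 = c(0.006, 0.012),
               SSP3 = c(0.010, 0.018)),
    income = list(SSP1 = c(0.015, 0.020), SSP2 = c(0.010, 0.015),
                  SSP3 = c(0.005, 0.010)),
    clim = list(RCP4.5 = c(0.98, 1.00), RCP6.0 = c(0.95, 0.99),
                RCP8.5 = c(0.90, 0.97)),
    yint2 = c(0.003, 0.010),
    ceiling = c(SSP1 = 1.10, SSP2 = 1.00, SSP3 = 0.90)
  )
}

#' Generate scenario drivers
#'
#' Builds the per-year exogenous paths that distinguish foresight scenarios:
#' population and per-capita income multipliers per region, the exogenous
#' yield-trend factor, water and climate yield multipliers per
#' region-commodity, and the scenario's adoption-ceiling adjustment (+10%
#' under SSP1, -10% under SSP3). `"static"` freezes every path at its base
#' value (all multipliers 1, ceiling factor 1), emulating a comparative-static
#' economic-surplus counterfactual inside the dynamic simulator.
#'
#' Under a common seed, pathway orderings hold region-by-region and year-by-
#' year (beyond the base year): SSP3 population growth exceeds SSP2 exceeds
#' SSP1; income growth is ordered the other way; climate multipliers satisfy
#' RCP4.5 >= RCP6.0 >= RCP8.5.
#'
#' @param pathway One of `"static"`, `"SSP1-RCP4.5"`, `"SSP2-RCP6.0"`,
#'   `"SSP3-RCP8.5"`.
#' @param world The `pe_world` the drivers will be simulated against.
#' @param seed Integer seed; the same seed gives comparable draws across
#'   pathways.
#' @return A list of class `pe_drivers` with tibbles `demographics`
#'   (`year`, `region`, `pop_mult`, `income_mult`) and `yield_paths`
#'   (`year`, `region`, `commodity`, `yint2`, `ywat`, `yclim`).
#' @export
generate_drivers <- function(pathway, world, seed = 1L) {
  known <- ssp_rcp_pathways()
  if (!is.character(pathway) || length(pathway) != 1 || !pathway %in% known) {
    rlang::abort(sprintf("unknown pathway '%s'; expected one of: %s",
                         paste(pathway, collapse = ","),
                         paste(known, collapse = ", ")))
  }
  years <- world_years(world)
  t_rel <- years - years[1]
  regions <- world$regions$region
  cms <- world$commodities$commodity
  n <- length(regions)
  rng <- driver_ranges()

  # draw order is fixed so that identical seeds give comparable draws
  # across pathways
  u <- withr::with_seed(seed, list(
    pop = stats::runif(n),
    income = stats::runif(n),
    clim = stats::runif(n),
    yint2 = stats::runif(n * length(cms))
  ))

  grid_rt <- tidyr::expand_grid(year = years, region = regions)
  grid_rct <- tidyr::expand_grid(year = years, region = regions, commodity = cms)

  if (pathway == "static") {
    demographics <- dplyr::mutate(grid_rt, pop_mult = 1, income_mult = 1)
    yield_paths <- dplyr::mutate(grid_rct, yint2 = 1, ywat = 1, yclim = 1)
    ceiling <- 1.0
    ssp <- rcp <- "static"
  } else {
    parts <- strsplit(pathway, "-", fixed = TRUE)[[1]]
    ssp <- parts[1]
    rcp <- sub("^RCP", "RCP", parts[2])
    map_range <- function(u, range) range[1] + u * (range[2] - range[1])
    g_pop <- map_range(u$pop, rng$pop[[ssp]])
    g_inc <- map_range(u$income, rng$income[[ssp]])
    clim_end <- map_range(u$clim, rng$clim[[rcp]])
    g_y <- map_range(u$yint2, rng$yint2)

    demographics <- grid_rt |>
      dplyr::mutate(
        t = .data$year - years[1],
        pop_mult = (1 + g_pop[match(.data$region, regions)])^.data$t,
        income_mult = (1 + g_inc[match(.data$region, regions)])^.data$t) |>
      dplyr::select(-"t")

    rc_key <- paste(rep(regions, each = length(cms)), rep(cms, times = n))
    span <- max(t_rel)
    yield_paths <- grid_rct |>
      dplyr::mutate(
        t = .data$year - years[1],
        i_rc = match(paste(.data$region, .data$commodity), rc_key),
        i_r = match(.data$region, regions),
        yint2 = (1 + g_y[.data$i_rc])^.data$t,
        ywat = 1,
        yclim = 1 + (clim_end[.data$i_r] - 1) * .data$t / span) |>
      dplyr::select(-"t", -"i_rc", -"i_r")
    ceiling <- unname(rng$ceiling[[ssp]])
  }

  structure(
    list(pathway = pathway, ssp = ssp, rcp = rcp,
         adoption_ceiling_factor = ceiling,
         demographics = demographics, yield_paths = yield_paths,
         horizon = world$horizon),
    class = "pe_drivers")
}

#' @export
print.pe_drivers <- function(x, ...) {
  cat(sprintf("<pe_drivers> %s (adoption ceiling factor %.2f), %d-%d\n",
              x$pathway, x$adoption_ceiling_factor, x$horizon[1], x$horizon[2]))
  invisible(x)
}

#' Define a technology option
#'
#' A research option is described by its research lag (years of R&D before
#' release), adoption lag (years over which diffusion approaches its
#' ceiling), per-target-region adoption ceilings `amax` (fraction of
#' harvested area), maximum expected yield changes `dy` (fractional), input
#' production-cost changes `dc` (fractional), probabilities of research
#' success `p`, and the cost assumptions: annual R&D cost (million US$ per
#' year of the research lag) and a dissemination cost per newly adopted
#' hectare (US$/ha).
#'
#' @param name Technology id.
#' @param research_lag,adoption_lag Lags in years.
#' @param annual_rd_cost Annual R&D cost, million US$.
#' @param dissemination_cost_per_ha Dissemination cost, US$/ha of marginal
#'   adopted area.
#' @param targets Tibble with columns `region`, `amax`, `dy`, `dc`, `p`.
#' @return A list of class `pe_technology`.
#' @export
technology_option <- function(name, research_lag, adoption_lag,
                              annual_rd_cost, dissemination_cost_per_ha,
                              targets) {
  targets <- tibble::as_tibble(targets)
  if (nrow(targets) == 0) rlang::abort("technology targets must be non-empty")
  stopifnot(all(c("region", "amax", "dy", "dc", "p") %in% names(targets)))
  if (any(targets$amax <= 0 | targets$amax > 1)) {
    rlang::abort("amax must lie in (0, 1]")
  }
  if (any(targets$dy <= -1)) rlang::abort("dy must exceed -1")
  if (any(targets$p < 0 | targets$p > 1)) rlang::abort("p must lie in [0, 1]")
  if (annual_rd_cost < 0 || dissemination_cost_per_ha < 0) {
    rlang::abort("costs must be non-negative")
  }
  structure(
    list(name = name, research_lag = as.integer(research_lag),
         adoption_lag = as.integer(adoption_lag),
         annual_rd_cost = annual_rd_cost,
         dissemination_cost_per_ha = dissemination_cost_per_ha,
         targets = targets),
    class = "pe_technology")
}

#' @export
print.pe_technology <- function(x, ...) {
  cat(sprintf(
    "<pe_technology> %s: research lag %d y, adoption lag %d y, %d targets, R&D %g M$/y, dissemination %g $/ha\n",
    x$name, x$research_lag, x$adoption_lag, nrow(x$targets),
    x$annual_rd_cost, x$dissemination_cost_per_ha))
  invisible(x)
}

#' Four potato research options
#'
#' Builds the four stylized potato technology fixtures used throughout the
#' package: improved seed systems, bacterial wilt-resistant varieties,
#' virus-resistant varieties, and late blight-resistant varieties. Lags,
#' annual R&D costs, dissemination costs and the parameter ranges (adoption
#' ceilings, expected yield changes, production-cost changes, probabilities
#' of success) follow the published expert-elicited summary for these
#' options; per-target-region values inside a range are drawn uniformly
#' under the given seed, since the country-level point estimates are not
#' public.
#'
#' Target sets are assigned by harvested-area rank among the world's target
#' regions, emulating the relative adopted-area ordering of the original
#' study: seed systems and late blight target all target regions, bacterial
#' wilt all but the largest producer, and virus resistance the smallest
#' `n_t - 2`.
#'
#' @param world A `pe_world` whose target regions receive the technologies.
#' @param seed Seed for the within-range uniform draws (fixed default so the
#'   fixtures are reproducible).
#' @return Named list of four `pe_technology` objects.
#' @export
potato_technologies <- function(world, seed = 1L) {
  focus <- focus_commodity(world)
  tg <- world$regions$region[world$regions$target]
  if (length(tg) == 0) rlang::abort("world has no target regions")
  areas <- world$calibration |>
    dplyr::filter(.data$commodity == focus, .data$region %in% tg) |>
    dplyr::arrange(dplyr::desc(.data$area_base))
  by_size <- areas$region
  n_t <- length(by_size)

  sets <- list(
    improved_seed_systems = by_size,
    bacterial_wilt_resistance = if (n_t > 1) by_size[-1] else by_size,
    virus_resistance = by_size[seq.int(min(3L, n_t), n_t)],
    late_blight_resistance = by_size
  )

  withr::with_seed(seed, {
    draw <- function(n, range) {
      if (range[1] == range[2]) rep(range[1], n) else stats::runif(n, range[1], range[2])
    }
    mk_targets <- function(regions, amax, dy, dc, p) {
      n <- length(regions)
      tibble::tibble(region = regions,
                     amax = draw(n, amax), dy = draw(n, dy),
                     dc = draw(n, dc), p = draw(n, p))
    }
    list(
      improved_seed_systems = technology_option(
        "improved_seed_systems", research_lag = 3L, adoption_lag = 5L,
        annual_rd_cost = 8, dissemination_cost_per_ha = 80,
        targets = mk_targets(sets$improved_seed_systems,
                             amax = c(0.03, 0.20), dy = c(0.20, 0.20),
                             dc = c(0.20, 0.20), p = c(0.60, 0.80))),
      bacterial_wilt_resistance = technology_option(
        "bacterial_wilt_resistance", research_lag = 10L, adoption_lag = 10L,
        annual_rd_cost = 4, dissemination_cost_per_ha = 50,
        targets = mk_targets(sets$bacterial_wilt_resistance,
                             amax = c(0.10, 0.60), dy = c(0.10, 0.30),
                             dc = c(0, 0), p = c(0.5, 0.5))),
      virus_resistance = technology_option(
        "virus_resistance", research_lag = 2L, adoption_lag = 10L,
        annual_rd_cost = 8, dissemination_cost_per_ha = 50,
        targets = mk_targets(sets$virus_resistance,
                             amax = c(0.15, 0.40), dy = c(0.40, 0.40),
                             dc = c(-0.05, -0.05), p = c(0.7, 0.7))),
      late_blight_resistance = technology_option(
        "late_blight_resistance", research_lag = 2L, adoption_lag = 10L,
        annual_rd_cost = 16, dissemination_cost_per_ha = 50,
        targets = mk_targets(sets$late_blight_resistance,
                             amax = c(0.10, 0.60), dy = c(0.12, 0.32),
                             dc = c(-0.05, -0.02), p = c(0.8, 0.8)))
    )
  })
}
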