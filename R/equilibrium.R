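# Internal: precompute the arrays the annual market solver works on.
# Rows follow the calibration table (one per region x commodity); columns of
# the elasticity matrices follow the commodity order of the world.
build_market_env <- function(world, drivers, shock = NULL) {
  years <- world_years(world)
  cms <- world$commodities$commodity
  cal <- world$calibration |>
    dplyr::arrange(match(.data$region, world$regions$region),
                   match(.data$commodity, cms))
  rc_key <- paste(cal$region, cal$commodity)
  n_rc <- nrow(cal)
  n_c <- length(cms)

  el_matrix <- function(el) {
    m <- matrix(0, n_rc, n_c)
    i <- match(paste(el$region, el$commodity), rc_key)
    j <- match(el$wrt, cms)
    m[cbind(i, j)] <- el$elast
    m
  }

  # demographics are per region: expand to region x commodity rows
  dem <- drivers$demographics
  dem_wide_pop <- tidyr::pivot_wider(dem, id_cols = "region",
                                     names_from = "year", values_from = "pop_mult")
  dem_wide_inc <- tidyr::pivot_wider(dem, id_cols = "region",
                                     names_from = "year", values_from = "income_mult")
  pop <- as.matrix(dem_wide_pop[match(cal$region, dem_wide_pop$region), as.character(years)])
  inc <- as.matrix(dem_wide_inc[match(cal$region, dem_wide_inc$region), as.character(years)])

  yp <- drivers$yield_paths
  yp$key <- paste(yp$region, yp$commodity)
  path_rc <- function(col) {
    w <- tidyr::pivot_wider(yp, id_cols = "key", names_from = "year",
                            values_from = dplyr::all_of(col))
    as.matrix(w[match(rc_key, w$key), as.character(years)])
  }
  yint2 <- path_rc("yint2")
  ywat <- path_rc("ywat")
  yclim <- path_rc("yclim")

  grid <- cal[, c("region", "commodity")]
  list(
    years = years, cms = cms, cal = cal, n_rc = n_rc, n_c = n_c,
    cm_idx = match(cal$commodity, cms),
    yint = cal$yield_base, area0 = cal$area_base, d0 = cal$demand_base,
    p0 = cal$price_base[match(cms, cal$commodity)],
    eps_y = cal$yield_price_elast,
    inc_e = cal$income_elast,
    e_area = el_matrix(world$area_elasticity),
    e_dem = el_matrix(world$demand_elasticity),
    pop = pop, inc = inc, yint2 = yint2, ywat = ywat, yclim = yclim,
    mult = shock_multiplier_matrix(shock, grid, years),
    base_gdem = vapply(cms, function(cm) sum(cal$demand_base[cal$commodity == cm]),
                       numeric(1))
  )
}

# Internal: supply, demand and scaled excess demand at log price deviations
market_at <- function(env, ti, logp) {
  own_lp <- logp[env$cm_idx]
  yield <- env$yint * env$yint2[, ti] * env$ywat[, ti] * env$yclim[, ti] *
    env$mult[, ti] * exp(env$eps_y * own_lp)
  area <- env$area0 * exp(drop(env$e_area %*% logp))
  supply <- yield * area
  demand <- env$d0 * env$pop[, ti] * env$inc[, ti]^env$inc_e *
    exp(drop(env$e_dem %*% logp))
  resid <- vapply(seq_len(env$n_c), function(j) {
    sum(demand[env$cm_idx == j]) - sum(supply[env$cm_idx == j])
  }, numeric(1))
  list(yield = yield, area = area, supply = supply, demand = demand,
       resid = resid, scaled = resid / env$base_gdem)
}

# Internal: damped Newton iteration on log world prices for one year
solve_year_env <- function(env, ti, logp_start, tol = 1e-8, max_iter = 50L) {
  logp <- logp_start
  st <- market_at(env, ti, logp)
  for (iter in seq_len(max_iter)) {
    if (max(abs(st$scaled)) <= tol) {
      return(list(logp = logp, state = st, iterations = iter - 1L))
    }
    h <- 1e-7
    jac <- matrix(0, env$n_c, env$n_c)
    for (j in seq_len(env$n_c)) {
      lp <- logp
      lp[j] <- lp[j] + h
      jac[, j] <- (market_at(env, ti, lp)$scaled - st$scaled) / h
    }
    step <- tryCatch(solve(jac, -st$scaled), error = function(e) NULL)
    if (is.null(step)) {
      rlang::abort("market solver failed: singular Jacobian")
    }
    lambda <- 1
    for (k in 1:30) {
      cand <- logp + lambda * step
      st_new <- market_at(env, ti, cand)
      if (max(abs(st_new$scaled)) < max(abs(st$scaled)) ||
          max(abs(st_new$scaled)) <= tol) break
      lambda <- lambda / 2
    }
    logp <- logp + lambda * step
    st <- st_new
  }
  if (max(abs(st$scaled)) <= tol) {
    return(list(logp = logp, state = st, iterations = max_iter))
  }
  rlang::abort(sprintf(
    "market solver did not converge after %d iterations; scaled residuals: %s",
    max_iter, paste(sprintf("%s=%.3g", env$cms, st$scaled), collapse = ", ")))
}

#' Yield response of one region-commodity cell
#'
#' Evaluates the multiplicative yield equation: the base yield times the
#' exogenous yield-trend, water and climate multipliers of the scenario,
#' times the technology shock multiplier, times own-price and input-price
#' power responses:
#' \deqn{Y = YInt \cdot YInt2_t \cdot YWat_t \cdot YClim_t \cdot
#'   (PS/PS_0)^{\varepsilon} \cdot (PF/PF_0)^{\eta} \cdot m_t.}
#' At the base year, base price and with no shock this returns the base
#' yield.
#'
#' @param world A `pe_world`.
#' @param drivers A `pe_drivers`.
#' @param region,commodity Cell identifiers.
#' @param year Simulation year.
#' @param price Domestic (= world) price, US$/t; must be positive.
#' @param shock Optional `pe_shock`.
#' @param input_price Input-price index (defaults to its base value, leaving
#'   the input-price channel inert).
#' @return Yield in t/ha.
#' @export
compute_yield <- function(world, drivers, region, commodity, year, price,
                          shock = NULL, input_price = NULL) {
  if (!is.finite(price) || price <= 0) {
    rlang::abort("price must be strictly positive")
  }
  cal <- dplyr::filter(world$calibration, .data$region == !!region,
                       .data$commodity == !!commodity)
  stopifnot(nrow(cal) == 1)
  yp <- dplyr::filter(drivers$yield_paths, .data$region == !!region,
                      .data$commodity == !!commodity, .data$year == !!year)
  stopifnot(nrow(yp) == 1)
  mult <- 1
  if (!is.null(shock)) {
    row <- dplyr::filter(shock$table, .data$region == !!region,
                         .data$commodity == !!commodity, .data$year == !!year)
    if (nrow(row) == 1) mult <- row$multiplier
  }
  pf <- if (is.null(input_price)) cal$input_price_base else input_price
  cal$yield_base * yp$yint2 * yp$ywat * yp$yclim * mult *
    (price / cal$price_base)^cal$yield_price_elast *
    (pf / cal$input_price_base)^cal$input_price_elast
}

#' Harvested-area response of one region-commodity cell
#'
#' Constant-elasticity area response calibrated at base prices:
#' `area = area_base * prod_j (P_j / P0_j)^(elast_j)` over all commodity
#' prices, with the own- and cross-price area elasticities of the world.
#'
#' @inheritParams compute_yield
#' @param prices Named vector of prices (US$/t) covering every commodity.
#' @return Area in kha.
#' @export
compute_area <- function(world, region, commodity, year, prices) {
  if (any(!is.finite(prices)) || any(prices <= 0)) {
    rlang::abort("prices must be strictly positive")
  }
  cal <- dplyr::filter(world$calibration, .data$region == !!region,
                       .data$commodity == !!commodity)
  stopifnot(nrow(cal) == 1)
  el <- dplyr::filter(world$area_elasticity, .data$region == !!region,
                      .data$commodity == !!commodity)
  p0 <- world$calibration |>
    dplyr::filter(.data$region == !!region) |>
    dplyr::select("commodity", "price_base")
  ratio <- prices[el$wrt] / p0$price_base[match(el$wrt, p0$commodity)]
  cal$area_base * prod(ratio^el$elast)
}

#' Food-demand response of one region-commodity cell
#'
#' Constant-elasticity demand calibrated at the base point, scaled by the
#' scenario's population multiplier (proportional) and income multiplier
#' raised to the income elasticity, with own- and cross-price terms:
#' `D = D0 * pop_t * inc_t^e_I * prod_j (P_j / P0_j)^(e_j)`.
#'
#' @inheritParams compute_area
#' @param drivers A `pe_drivers`.
#' @return Demand in kt.
#' @export
compute_demand <- function(world, drivers, region, commodity, year, prices) {
  if (any(!is.finite(prices)) || any(prices <= 0)) {
    rlang::abort("prices must be strictly positive")
  }
  cal <- dplyr::filter(world$calibration, .data$region == !!region,
                       .data$commodity == !!commodity)
  stopifnot(nrow(cal) == 1)
  el <- dplyr::filter(world$demand_elasticity, .data$region == !!region,
                      .data$commodity == !!commodity)
  p0 <- world$calibration |>
    dplyr::filter(.data$region == !!region) |>
    dplyr::select("commodity", "price_base")
  dem <- dplyr::filter(drivers$demographics, .data$region == !!region,
                       .data$year == !!year)
  stopifnot(nrow(dem) == 1)
  ratio <- prices[el$wrt] / p0$price_base[match(el$wrt, p0$commodity)]
  cal$demand_base * dem$pop_mult * dem$income_mult^cal$income_elast *
    prod(ratio^el$elast)
}

#' Global excess demand at candidate world prices
#'
#' Sums demand minus supply over all regions at the given world-price vector
#' (domestic prices equal world prices under the default perfect price
#' transmission). At the base year with base prices and no shock the
#' residual is zero for every commodity, by calibration.
#'
#' @inheritParams compute_demand
#' @param shock Optional `pe_shock`.
#' @param prices Named vector of candidate world prices (US$/t), one per
#'   commodity.
#' @return Named numeric vector of per-commodity residuals (kt).
#' @export
excess_demand <- function(world, drivers, year, prices, shock = NULL) {
  if (any(!is.finite(prices)) || any(prices <= 0)) {
    rlang::abort("prices must be strictly positive")
  }
  env <- build_market_env(world, drivers, shock)
  ti <- match(year, env$years)
  if (is.na(ti)) rlang::abort(sprintf("year %s outside horizon", year))
  logp <- log(prices[env$cms] / env$p0)
  st <- market_at(env, ti, logp)
  stats::setNames(st$resid, env$cms)
}

slice_from_state <- function(env, year, logp, st) {
  prices <- env$p0 * exp(logp)
  tibble::tibble(
    year = year,
    region = env$cal$region,
    commodity = env$cal$commodity,
    world_price = prices[env$cm_idx],
    price = prices[env$cm_idx],
    yield = unname(st$yield),
    area = unname(st$area),
    supply = unname(st$supply),
    demand = unname(st$demand),
    net_trade = unname(st$supply - st$demand))
}

#' Solve the market equilibrium of a single year
#'
#' Finds the world-price vector at which global supply equals global demand
#' for every commodity, by damped Newton iteration on log prices. The scaled
#' residual (excess demand relative to base-year global demand) is driven
#' below `tol` for every commodity.
#'
#' @inheritParams excess_demand
#' @param start_prices Optional named starting prices (typically the previous
#'   year's solution); defaults to base prices.
#' @param tol Convergence tolerance on the scaled excess demand.
#' @param max_iter Maximum Newton iterations before a diagnostic error.
#' @return List with `prices` (named vector), `slice` (the per-region
#'   trajectory tibble for the year) and `iterations`.
#' @export
solve_year <- function(world, drivers, year, shock = NULL,
                       start_prices = NULL, tol = 1e-8, max_iter = 50L) {
  env <- build_market_env(world, drivers, shock)
  ti <- match(year, env$years)
  if (is.na(ti)) rlang::abort(sprintf("year %s outside horizon", year))
  logp <- if (is.null(start_prices)) rep(0, env$n_c) else
    log(start_prices[env$cms] / env$p0)
  sol <- solve_year_env(env, ti, logp, tol = tol, max_iter = max_iter)
  list(prices = stats::setNames(env$p0 * exp(sol$logp), env$cms),
       slice = slice_from_state(env, year, sol$logp, sol$state),
       iterations = sol$iterations)
}

#' Run a full scenario trajectory
#'
#' Solves the market year by year over the world's horizon, warm-starting
#' each year at the previous year's prices (recursive-dynamic structure).
#' With no shock and static drivers every year reproduces the base-year
#' equilibrium; applying a null shock (zero yield and cost change, or zero
#' probability of success) reproduces the baseline bit-for-bit.
#'
#' @inheritParams solve_year
#' @return A tibble of class `pe_trajectory` with columns `year`, `region`,
#'   `commodity`, `world_price`, `price`, `yield`, `area`, `supply`,
#'   `demand`, `net_trade`; solver diagnostics are stored in attributes
#'   `iterations` and `pathway`.
#' @export
run_scenario <- function(world, drivers, shock = NULL, tol = 1e-8,
                         max_iter = 50L) {
  env <- build_market_env(world, drivers, shock)
  logp <- rep(0, env$n_c)
  slices <- vector("list", length(env$years))
  iters <- integer(length(env$years))
  for (ti in seq_along(env$years)) {
    sol <- tryCatch(
      solve_year_env(env, ti, logp, tol = tol, max_iter = max_iter),
      error = function(e) {
        rlang::abort(sprintf("year %d: %s", env$years[ti], conditionMessage(e)))
      })
    logp <- sol$logp
    slices[[ti]] <- slice_from_state(env, env$years[ti], logp, sol$state)
    iters[ti] <- sol$iterations
  }
  out <- purrr::list_rbind(slices)
  structure(out,
            class = c("pe_trajectory", class(out)),
            iterations = iters,
            pathway = drivers$pathway,
            shock_name = if (is.null(shock)) NA_character_ else shock$tech$name)
}

#' @export
tidy.pe_trajectory <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "pe_trajectory")
  attr(out, "iterations") <- NULL
  attr(out, "pathway") <- NULL
  attr(out, "shock_name") <- NULL
  out
}

#' @export
glance.pe_trajectory <- function(x, ...) {
  tibble::tibble(
    pathway = attr(x, "pathway"),
    shock = attr(x, "shock_name"),
    years = length(unique(x$year)),
    regions = length(unique(x$region)),
    commodities = length(unique(x$commodity)),
    mean_iterations = mean(attr(x, "iterations")))
}

#' Write a trajectory to CSV
#'
#' @param trajectory A `pe_trajectory`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  readr::write_csv(tidy(trajectory), path)
  invisible(path)
}
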