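#' Proportional supply shift of the economic surplus model
#'
#' In the comparative-static economic surplus framework, a technology that
#' raises yields by a maximum fraction `dy` and changes input costs by a
#' fraction `dc`, succeeds with probability `p` and is adopted on a fraction
#' `a_t` of the harvested area shifts the supply curve vertically by the
#' proportion
#' \deqn{k_t = \left(\frac{\Delta Y}{\varepsilon_s} -
#'   \frac{\Delta C}{1 + \Delta Y}\right) \times p \times A_t,}
#' where \eqn{\varepsilon_s} is the price elasticity of supply.
#'
#' @param dy Maximum expected fractional yield change (> -1).
#' @param eps_s Price elasticity of supply (> 0).
#' @param dc Fractional input production-cost change.
#' @param p Probability of research success in [0, 1].
#' @param a_t Adoption rate (fraction of harvested area) in [0, 1].
#' @return The proportional vertical supply shift `k_t`; 0 when `a_t = 0`.
#' @export
supply_shift_k <- function(dy, eps_s, dc = 0, p = 1, a_t = 1) {
  if (any(eps_s <= 0)) rlang::abort("eps_s must be strictly positive")
  if (any(dy <= -1)) rlang::abort("dy must exceed -1")
  if (any(p < 0 | p > 1)) rlang::abort("p must lie in [0, 1]")
  if (any(a_t < 0 | a_t > 1)) rlang::abort("a_t must lie in [0, 1]")
  (dy / eps_s - dc / (1 + dy)) * p * a_t
}

#' Yield-trend shift equivalent of a technology
#'
#' The simulator represents research-induced productivity growth as an upward
#' shift of the exogenous yield trend rather than a direct supply shift. The
#' fully adopted, success-weighted shift is
#' \deqn{\Delta YInt2 = \left(\Delta Y - \frac{\Delta C}{1 + \Delta Y}\right)
#'   \times p,}
#' which collapses to `dy * p` when input costs are unchanged and decreases
#' in `dc` (a cost saving, `dc < 0`, adds to the shift).
#'
#' @inheritParams supply_shift_k
#' @return The fractional yield-trend shift at full adoption.
#' @export
yield_trend_shift <- function(dy, dc = 0, p = 1) {
  if (any(dy <= -1)) rlang::abort("dy must exceed -1")
  if (any(p < 0 | p > 1)) rlang::abort("p must lie in [0, 1]")
  (dy - dc / (1 + dy)) * p
}

#' Build the shock specification for a technology under a scenario
#'
#' Translates a [technology_option()] into per-region, per-year yield
#' multipliers for the focus commodity. For each target region the adoption
#' curve is released after the research lag with its midpoint half the
#' adoption lag later; the ceiling is adjusted by the scenario's
#' adoption-ceiling factor (capped at 1). The region's effective multiplier
#' in year *t* is `1 + dYInt2 * A(t)`, reading the yield-trend shift as the
#' fully adopted effect and the adoption rate as the area share under the new
#' technology. Non-target regions, non-focus commodities and pre-release
#' years keep a multiplier of exactly 1.
#'
#' @param tech A `pe_technology`.
#' @param world A `pe_world`; all the technology's target regions must exist
#'   in it.
#' @param drivers A `pe_drivers` supplying the adoption-ceiling factor
#'   (optional: defaults to factor 1).
#' @param a0_frac Initial adoption rate as a fraction of the (adjusted)
#'   ceiling at the release year.
#' @return A list of class `pe_shock` with the technology, the per-target
#'   adoption curves, and tibble `table` (`year`, `region`, `commodity`,
#'   `adoption`, `dyint2`, `multiplier`) covering target regions; cells
#'   absent from the table are unshocked.
#' @export
build_shock <- function(tech, world, drivers = NULL, a0_frac = 0.005) {
  missing_rg <- setdiff(tech$targets$region, world$regions$region)
  if (length(missing_rg) > 0) {
    rlang::abort(sprintf("target region(s) absent from world: %s",
                         paste(missing_rg, collapse = ", ")))
  }
  years <- world_years(world)
  if (tech$research_lag + tech$adoption_lag > length(years) - 1) {
    rlang::abort(sprintf(
      "horizon (%d years) shorter than research + adoption lag (%d + %d)",
      length(years), tech$research_lag, tech$adoption_lag))
  }
  ceiling_factor <- if (is.null(drivers)) 1 else drivers$adoption_ceiling_factor
  focus <- focus_commodity(world)
  release <- years[1] + tech$research_lag
  tmid <- release + tech$adoption_lag / 2

  rows <- purrr::pmap(tech$targets, function(region, amax, dy, dc, p) {
    amax_eff <- min(1, amax * ceiling_factor)
    curve <- adoption_curve(amax_eff, t0 = release, tmid = tmid,
                            a0 = a0_frac * amax_eff)
    dyint2 <- yield_trend_shift(dy, dc, p)
    adoption <- ifelse(years >= release, adoption_rate(curve, years), 0)
    list(
      curve = curve,
      table = tibble::tibble(
        year = years, region = region, commodity = focus,
        adoption = adoption, dyint2 = dyint2,
        multiplier = 1 + dyint2 * adoption))
  })
  curves <- purrr::map(rows, "curve")
  names(curves) <- tech$targets$region

  structure(
    list(tech = tech, release_year = release, tmid = tmid,
         ceiling_factor = ceiling_factor,
         curves = curves,
         table = purrr::list_rbind(purrr::map(rows, "table"))),
    class = "pe_shock")
}

#' Build a constant supply-side shock
#'
#' Applies a fixed focus-crop yield multiplier to the given regions from a
#' release year onward, with full adoption and no research or dissemination
#' costs. This is the sustained one-time productivity increase of the
#' comparative-static surplus model, and is the shock used when verifying
#' the simulator against the closed-form surplus oracle.
#'
#' @param world A `pe_world`.
#' @param regions Regions to shock (become the target group).
#' @param multiplier Yield multiplier (> 0) applied from `release_year` on.
#' @param release_year First shocked year (default: first horizon year).
#' @return A `pe_shock`.
#' @export
constant_shock <- function(world, regions, multiplier,
                           release_year = world$horizon[1]) {
  if (multiplier <= 0) rlang::abort("multiplier must be positive")
  years <- world_years(world)
  focus <- focus_commodity(world)
  tech <- technology_option(
    "constant_shock", research_lag = 0L, adoption_lag = 0L,
    annual_rd_cost = 0, dissemination_cost_per_ha = 0,
    targets = tibble::tibble(region = regions, amax = 1,
                             dy = multiplier - 1, dc = 0, p = 1))
  table <- tidyr::expand_grid(year = years, region = regions) |>
    dplyr::mutate(commodity = focus,
                  adoption = as.numeric(.data$year >= release_year),
                  dyint2 = multiplier - 1,
                  multiplier = 1 + .data$dyint2 * .data$adoption)
  structure(
    list(tech = tech, release_year = release_year, tmid = release_year,
         ceiling_factor = 1, curves = list(), table = table),
    class = "pe_shock")
}

#' @export
print.pe_shock <- function(x, ...) {
  cat(sprintf(
    "<pe_shock> %s: release %d, 50%% adoption %.1f, ceiling factor %.2f, %d target regions\n",
    x$tech$name, x$release_year, x$tmid, x$ceiling_factor, length(x$curves)))
  invisible(x)
}

#' @export
tidy.pe_shock <- function(x, ...) x$table

# multiplier matrix lookup used by the solver: rows follow `grid` (region,
# commodity), one column per year; 1 wherever the shock table is silent
shock_multiplier_matrix <- function(shock, grid, years) {
  mult <- matrix(1, nrow = nrow(grid), ncol = length(years))
  if (is.null(shock)) return(mult)
  tab <- shock$table
  i <- match(paste(tab$region, tab$commodity), paste(grid$region, grid$commodity))
  j <- match(tab$year, years)
  keep <- !is.na(i) & !is.na(j)
  mult[cbind(i[keep], j[keep])] <- tab$multiplier[keep]
  mult
}

#' R&D and dissemination cost stream of a technology
#'
#' The R&D cost accrues as a constant annual amount in each year of the
#' research lag (starting at the first horizon year); the dissemination cost
#' is a fixed amount per hectare of *marginal* (newly adopted) area in each
#' adoption year. The returned stream covers the full horizon.
#'
#' @param tech A `pe_technology`.
#' @param marginal_path Tibble with columns `year` and `marginal` (kha of
#'   newly adopted area per year), e.g. summed over target regions from
#'   [adopted_area_path()].
#' @param horizon Integer `c(first, last)` simulation years.
#' @return Tibble `year`, `rd_cost`, `dissemination_cost`, `cost`
#'   (million US$).
#' @export
cost_stream <- function(tech, marginal_path, horizon) {
  years <- seq.int(horizon[1], horizon[2])
  rd_years <- years[1] + seq_len(tech$research_lag) - 1L
  marginal <- rep(0, length(years))
  if (!is.null(marginal_path) && nrow(marginal_path) > 0) {
    i <- match(marginal_path$year, years)
    keep <- !is.na(i)
    marginal[i[keep]] <- marginal_path$marginal[keep]
  }
  tibble::tibble(
    year = years,
    rd_cost = ifelse(years %in% rd_years, tech$annual_rd_cost, 0),
    # kha -> ha is *1000; US$ -> million US$ is /1e6
    dissemination_cost = tech$dissemination_cost_per_ha * marginal * 1000 / 1e6
  ) |>
    dplyr::mutate(cost = .data$rd_cost + .data$dissemination_cost)
}
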