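#' Consumer surplus under a linearized demand curve
#'
#' Linearizes the demand curve at the observed equilibrium point `(Q, P)`
#' using the own-price demand elasticity (slope `elasticity * Q / P`) and
#' returns the triangle between the price line and the resulting price
#' intercept: \eqn{CS = Q P / (2 |\varepsilon|)}. Units follow the inputs
#' (price x quantity).
#'
#' @param price,quantity Positive equilibrium price and quantity.
#' @param elasticity Own-price demand elasticity (must be negative).
#' @return Consumer surplus level; vectorized over the inputs.
#' @export
consumer_surplus <- function(price, quantity, elasticity) {
  if (any(elasticity >= 0)) {
    rlang::abort("demand elasticity must be negative")
  }
  if (any(price <= 0) || any(quantity <= 0)) {
    rlang::abort("price and quantity must be positive")
  }
  quantity * price / (2 * abs(elasticity))
}

#' Producer surplus under a linearized supply curve
#'
#' Linearizes the supply curve at `(Q, P)` with slope `eps_s * Q / P`. When
#' `eps_s >= 1` the price intercept is non-negative and the surplus is the
#' triangle \eqn{QP/(2\varepsilon_s)}; when `eps_s < 1` the linear supply
#' crosses the quantity axis at positive quantity, so the surplus is the
#' trapezoid above the curve truncated at price zero:
#' \eqn{PQ(1 - \varepsilon_s/2)}. The two branches agree at
#' `eps_s = 1` (both give `QP/2`).
#'
#' @param price,quantity Positive equilibrium price and quantity.
#' @param eps_s Price elasticity of supply (must be positive).
#' @return Producer surplus level; vectorized over the inputs.
#' @export
producer_surplus <- function(price, quantity, eps_s) {
  if (any(eps_s <= 0)) rlang::abort("supply elasticity must be positive")
  if (any(price <= 0) || any(quantity <= 0)) {
    rlang::abort("price and quantity must be positive")
  }
  ifelse(eps_s >= 1,
         quantity * price / (2 * eps_s),
         price * quantity * (1 - eps_s / 2))
}

#' Closed-form economic-surplus changes (verification oracle)
#'
#' The textbook comparative-static surplus model for a parallel vertical
#' supply shift `k` (proportion of the initial price) with linear supply and
#' demand through `(Q0, P0)`: the relative price fall is
#' \eqn{Z = k \varepsilon_s / (\varepsilon_s + \eta)} and
#' \deqn{\Delta CS = P_0 Q_0 Z (1 + 0.5 Z \eta), \quad
#'   \Delta PS = P_0 Q_0 (k - Z)(1 + 0.5 Z \eta).}
#' Serves as the independent small-world oracle against which the simulator's
#' welfare accounting is verified.
#'
#' @param k Proportional vertical supply shift; must satisfy the safeguard
#'   `k < eps_s / (1 + eta)`.
#' @param p0,q0 Initial equilibrium price and quantity.
#' @param eta Own-price demand elasticity magnitude (positive number).
#' @param eps_s Price elasticity of supply (positive).
#' @return Tibble with `dcs`, `dps`, `dtotal` in price x quantity units.
#' @export
alston_surplus <- function(k, p0, q0, eta, eps_s) {
  if (any(p0 <= 0) || any(q0 <= 0) || any(eta <= 0) || any(eps_s <= 0)) {
    rlang::abort("p0, q0, eta and eps_s must be positive")
  }
  if (any(k < 0) || any(k >= eps_s / (1 + eta))) {
    rlang::abort("k outside safeguard: need 0 <= k < eps_s / (1 + eta)")
  }
  z <- k * eps_s / (eps_s + eta)
  dcs <- p0 * q0 * z * (1 + 0.5 * z * eta)
  dps <- p0 * q0 * (k - z) * (1 + 0.5 * z * eta)
  tibble::tibble(dcs = dcs, dps = dps, dtotal = dcs + dps)
}

#' Net present value of an annual stream
#'
#' Discounts an annual stream with `t = 0` at its first entry (the first
#' simulation year): \eqn{NPV = \sum_t s_t / (1+r)^t}.
#'
#' @param stream Numeric vector of annual amounts (million US$).
#' @param rate Discount rate (> -1); the study default is 10%.
#' @return The net present value.
#' @export
npv <- function(stream, rate = 0.10) {
  if (rate <= -1) rlang::abort("rate must exceed -1")
  sum(stream / (1 + rate)^(seq_along(stream) - 1))
}

#' Internal rate of return
#'
#' Returns the smallest real discount rate above -100% at which the stream's
#' net present value is zero, found from the roots of the NPV polynomial and
#' polished by Newton iteration to |NPV| <= 1e-10 (relative to the stream
#' scale).
#'
#' @param stream Numeric vector with at least one sign change.
#' @return The internal rate of return.
#' @export
irr <- function(stream) {
  s <- stream[seq_len(max(which(stream != 0), 0))]
  if (length(s) < 2 || min(s) >= 0 || max(s) <= 0) {
    rlang::abort("IRR undefined: stream must contain a sign change")
  }
  roots <- polyroot(s)  # roots in x = 1/(1+r)
  x <- Re(roots[abs(Im(roots)) < 1e-8 * (1 + abs(roots))])
  x <- x[x > 0]
  if (length(x) == 0) {
    rlang::abort("IRR undefined: no real root above -100%")
  }
  candidates <- sort(1 / x - 1)
  r <- candidates[1]
  # Newton polish
  t <- seq_along(stream) - 1
  scale <- max(abs(stream))
  for (i in 1:100) {
    f <- sum(stream / (1 + r)^t)
    if (abs(f) <= 1e-10 * scale) break
    fp <- sum(-t * stream / (1 + r)^(t + 1))
    if (fp == 0) break
    r <- r - f / fp
  }
  r
}

#' Modified internal rate of return
#'
#' Compounds the positive entries forward to the final period at the
#' reinvestment rate, discounts the negative entries to the first period at
#' the finance rate, and returns
#' \eqn{(FV_+ / |PV_-|)^{1/n} - 1} with `n` the number of periods after the
#' first. Both rates default to the study's 10% discount rate.
#'
#' @param stream Numeric vector with at least one negative and one positive
#'   entry.
#' @param finance_rate Rate applied to negative flows.
#' @param reinvest_rate Rate applied to positive flows.
#' @return The modified internal rate of return.
#' @export
mirr <- function(stream, finance_rate = 0.10, reinvest_rate = 0.10) {
  if (min(stream) >= 0 || max(stream) <= 0) {
    rlang::abort("MIRR undefined: stream needs both negative and positive entries")
  }
  n <- length(stream) - 1
  t <- seq_along(stream) - 1
  pos <- pmax(stream, 0)
  neg <- pmin(stream, 0)
  fv <- sum(pos * (1 + reinvest_rate)^(n - t))
  pv <- sum(neg / (1 + finance_rate)^t)
  (fv / abs(pv))^(1 / n) - 1
}

#' Regional supply elasticity of the focus crop
#'
#' The synthetic regional supply curve aggregates the yield and area
#' responses; its price elasticity is taken as the sum of the yield own-price
#' elasticity and the area own-price elasticity.
#'
#' @param world A `pe_world`.
#' @param commodity Commodity id (defaults to the focus commodity).
#' @return Tibble `region`, `eps_s`.
#' @export
region_supply_elasticity <- function(world, commodity = focus_commodity(world)) {
  own_area <- world$area_elasticity |>
    dplyr::filter(.data$commodity == !!commodity, .data$wrt == !!commodity) |>
    dplyr::select("region", area_elast = "elast")
  world$calibration |>
    dplyr::filter(.data$commodity == !!commodity) |>
    dplyr::select("region", "yield_price_elast") |>
    dplyr::left_join(own_area, by = "region") |>
    dplyr::mutate(eps_s = .data$yield_price_elast + .data$area_elast) |>
    dplyr::select("region", "eps_s")
}

# Internal: vertical supply-shift proportion equivalent to a yield
# multiplier m on a constant-elasticity supply curve: (1-k)^(-eps_s) = m
shift_from_multiplier <- function(multiplier, eps_s) {
  1 - multiplier^(-1 / eps_s)
}

#' Per-year surplus changes between a baseline and a shocked trajectory
#'
#' Measures welfare on the focus-crop market only (changes in all other
#' markets are reflected in its equilibrium, and counting them again would
#' double-count). For each region and year, demand and supply curves are
#' linearized at the equilibrium points and the change is integrated between
#' the baseline and shocked prices:
#' \deqn{\Delta CS = (P_0 - P_1)(D_0 + D_1)/2, \quad
#'   \Delta PS = (P_1 - (1 - k) P_0)(S_0 + S_1)/2,}
#' where `k` is the vertical supply-shift proportion implied by the region's
#' shock multiplier (zero for non-target regions, so their producer change is
#' a pure price effect). Region results are summed into `target`,
#' `non_target` and `all` groups; the groups are additive by construction.
#'
#' @param baseline,shocked `pe_trajectory` objects over the same world and
#'   horizon.
#' @param world The `pe_world` both trajectories were solved on.
#' @param shock The `pe_shock` that produced `shocked` (defines the target
#'   group and the shift).
#' @return Tibble `year`, `group`, `dcs`, `dps` (million US$).
#' @export
welfare_change <- function(baseline, shocked, world, shock) {
  if (!identical(sort(unique(baseline$year)), sort(unique(shocked$year)))) {
    rlang::abort("baseline and shocked trajectories cover different horizons")
  }
  focus <- focus_commodity(world)
  eps_s <- region_supply_elasticity(world)
  targets <- shock$tech$targets$region

  base <- baseline |>
    dplyr::filter(.data$commodity == focus) |>
    dplyr::select("year", "region", p0 = "price", d0 = "demand", s0 = "supply")
  shk <- shocked |>
    dplyr::filter(.data$commodity == focus) |>
    dplyr::select("year", "region", p1 = "price", d1 = "demand", s1 = "supply")
  mult <- shock$table |>
    dplyr::filter(.data$commodity == focus) |>
    dplyr::select("year", "region", "multiplier")

  per_region <- base |>
    dplyr::inner_join(shk, by = c("year", "region")) |>
    dplyr::left_join(mult, by = c("year", "region")) |>
    dplyr::left_join(eps_s, by = "region") |>
    dplyr::mutate(
      multiplier = dplyr::coalesce(.data$multiplier, 1),
      k = shift_from_multiplier(.data$multiplier, .data$eps_s),
      # US$/t x kt = thousand US$; /1000 -> million US$
      dcs = (.data$p0 - .data$p1) * (.data$d0 + .data$d1) / 2 / 1000,
      dps = (.data$p1 - (1 - .data$k) * .data$p0) * (.data$s0 + .data$s1) / 2 / 1000,
      group = ifelse(.data$region %in% targets, "target", "non_target"))

  grouped <- per_region |>
    dplyr::group_by(.data$year, .data$group) |>
    dplyr::summarise(dcs = sum(.data$dcs), dps = sum(.data$dps),
                     .groups = "drop")
  all <- grouped |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(dcs = sum(.data$dcs), dps = sum(.data$dps),
                     .groups = "drop") |>
    dplyr::mutate(group = "all")
  dplyr::bind_rows(grouped, all) |>
    dplyr::arrange(.data$year, .data$group)
}

# Internal: marginal adopted area (kha/year) summed over target regions,
# computed from the shocked trajectory's realized harvested areas
marginal_adopted <- function(shocked, world, shock) {
  focus <- focus_commodity(world)
  shock$table |>
    dplyr::filter(.data$commodity == focus) |>
    dplyr::inner_join(
      dplyr::select(dplyr::filter(shocked, .data$commodity == focus),
                    "year", "region", "area"),
      by = c("year", "region")) |>
    dplyr::group_by(.data$region) |>
    dplyr::arrange(.data$year, .by_group = TRUE) |>
    dplyr::mutate(adopted = .data$adoption * .data$area,
                  marginal = pmax(0, .data$adopted - dplyr::lag(.data$adopted, default = 0))) |>
    dplyr::ungroup() |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(adopted = sum(.data$adopted),
                     marginal = sum(.data$marginal), .groups = "drop")
}

#' Benefit-cost report for one technology under one scenario
#'
#' Combines the per-year surplus changes with the technology's R&D and
#' dissemination cost stream into the investment metrics used for priority
#' setting: NPVs of producer surplus, consumer surplus and net welfare
#' benefits (surplus changes minus costs), IRR and MIRR — for the
#' all-countries and target-countries-only aggregations. Costs are identical
#' across aggregations; dissemination costs follow the marginal adopted area
#' realized in the shocked run. IRR is `NA` when the net stream has no sign
#' change.
#'
#' @inheritParams welfare_change
#' @param discount_rate Discount rate for the NPVs (default 10%).
#' @param finance_rate,reinvest_rate MIRR rates (default to the discount
#'   rate).
#' @return A tibble of class `pe_welfare` with one row per aggregation
#'   (`all`, `target`): NPV components, `irr`, `mirr`, and a nested `stream`
#'   tibble of the undiscounted annual flows for audit.
#' @export
welfare_report <- function(baseline, shocked, world, shock,
                           discount_rate = 0.10,
                           finance_rate = discount_rate,
                           reinvest_rate = discount_rate) {
  wc <- welfare_change(baseline, shocked, world, shock)
  adopted <- marginal_adopted(shocked, world, shock)
  costs <- cost_stream(shock$tech, adopted, world$horizon)

  one <- function(agg) {
    grp <- if (agg == "all") "all" else "target"
    w <- dplyr::filter(wc, .data$group == grp) |> dplyr::arrange(.data$year)
    stream <- w |>
      dplyr::left_join(dplyr::select(costs, "year", "cost"), by = "year") |>
      dplyr::mutate(net = .data$dcs + .data$dps - .data$cost)
    irr_val <- tryCatch(irr(stream$net), error = function(e) NA_real_)
    tibble::tibble(
      technology = shock$tech$name,
      aggregation = agg,
      dps_npv = npv(stream$dps, discount_rate),
      dcs_npv = npv(stream$dcs, discount_rate),
      cost_npv = npv(stream$cost, discount_rate),
      net_npv = npv(stream$net, discount_rate),
      irr = irr_val,
      mirr = tryCatch(mirr(stream$net, finance_rate, reinvest_rate),
                      error = function(e) NA_real_),
      stream = list(stream))
  }
  out <- dplyr::bind_rows(one("all"), one("target"))
  class(out) <- c("pe_welfare", class(out))
  out
}

#' Rank technologies by an investment metric
#'
#' Orders a set of welfare-report rows by descending net-benefit NPV, IRR or
#' MIRR. Ties are broken alphabetically by technology name so the ordering
#' is deterministic.
#'
#' @param reports Tibble of welfare-report rows (e.g. several
#'   [welfare_report()] results bound together, or a study report).
#' @param metric One of `"npv"`, `"irr"`, `"mirr"`.
#' @param aggregation Aggregation to rank within (default `"all"`); ignored
#'   when the input has no `aggregation` column.
#' @param pathway Optional scenario filter when the input has a `pathway`
#'   column.
#' @return The filtered rows, ordered, with a `rank` column.
#' @export
rank_technologies <- function(reports, metric = c("npv", "irr", "mirr"),
                              aggregation = "all", pathway = NULL) {
  metric <- rlang::arg_match(metric)
  col <- c(npv = "net_npv", irr = "irr", mirr = "mirr")[[metric]]
  if (!col %in% names(reports)) {
    rlang::abort(sprintf("metric column '%s' missing from reports", col))
  }
  out <- reports
  if ("aggregation" %in% names(out)) {
    out <- dplyr::filter(out, .data$aggregation == !!aggregation)
  }
  if (!is.null(pathway) && "pathway" %in% names(out)) {
    pw <- pathway
    out <- dplyr::filter(out, .data$pathway == pw)
  }
  out |>
    dplyr::arrange(dplyr::desc(.data[[col]]), .data$technology) |>
    dplyr::mutate(rank = dplyr::row_number())
}
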