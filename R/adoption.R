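#' Solve logistic adoption-curve parameters from two anchor points
#'
#' Technology diffusion follows the logistic curve
#' \deqn{A(t) = A_{max} / (1 + e^{-(\alpha + \beta t)})}
#' whose two parameters are pinned down by two points on the curve: the
#' initial adoption rate `a0` at year `t0` and 50% of the ceiling at year
#' `tmid`. The closed form is
#' \eqn{\beta = \log(A_{max}/A_0 - 1)/(t_{mid} - t_0)} and
#' \eqn{\alpha = -\beta t_{mid}}, which reproduces both anchors exactly.
#'
#' @param a0 Initial adoption rate at `t0`; must satisfy `0 < a0 < amax/2`
#'   (a rising logistic cannot pass through `a0 >= amax/2` before `tmid`).
#' @param amax Adoption ceiling, fraction of harvested area in (0, 1].
#' @param t0 Year of initial adoption.
#' @param tmid Year at which adoption reaches `amax/2`; `tmid > t0`.
#' @return Named list with `alpha` and `beta` (`beta > 0`).
#' @export
solve_logistic_params <- function(a0, amax, t0, tmid) {
  if (amax <= 0 || amax > 1) rlang::abort("amax must lie in (0, 1]")
  if (a0 <= 0 || a0 >= amax) rlang::abort("a0 must satisfy 0 < a0 < amax")
  if (t0 >= tmid) rlang::abort("t0 must precede tmid")
  if (a0 >= amax / 2) {
    rlang::abort(
      "a0 must be below amax/2: a rising logistic through (t0, a0) cannot reach amax/2 later at tmid")
  }
  beta <- log(amax / a0 - 1) / (tmid - t0)
  list(alpha = -beta * tmid, beta = beta)
}

#' Construct an adoption curve
#'
#' Convenience wrapper around [solve_logistic_params()] that stores the
#' anchors alongside the solved parameters. By default the initial adoption
#' rate is 0.5% of the ceiling at the release year and the midpoint sits half
#' the adoption lag after release, so the ceiling is effectively reached by
#' the end of the adoption lag.
#'
#' @param amax Adoption ceiling (fraction of harvested area).
#' @param t0 Year of initial adoption (technology release year).
#' @param tmid Year of 50% adoption.
#' @param a0 Initial adoption rate at `t0` (default `0.005 * amax`).
#' @return A list of class `pe_adoption`.
#' @export
adoption_curve <- function(amax, t0, tmid, a0 = 0.005 * amax) {
  par <- solve_logistic_params(a0, amax, t0, tmid)
  structure(list(amax = amax, a0 = a0, t0 = t0, tmid = tmid,
                 alpha = par$alpha, beta = par$beta),
            class = "pe_adoption")
}

#' Evaluate an adoption curve
#'
#' @param curve A `pe_adoption` from [adoption_curve()].
#' @param t Year(s) at which to evaluate; vectorized.
#' @return Adopted fraction of harvested area, in (0, amax), monotone
#'   non-decreasing in `t` and approaching `amax` as `t` grows.
#' @export
adoption_rate <- function(curve, t) {
  curve$amax / (1 + exp(-(curve$alpha + curve$beta * t)))
}

#' @export
print.pe_adoption <- function(x, ...) {
  cat(sprintf(
    "<pe_adoption> amax %.3f, a0 %.4f @ %s, 50%% @ %s (alpha %.4f, beta %.4f)\n",
    x$amax, x$a0, format(x$t0), format(x$tmid), x$alpha, x$beta))
  invisible(x)
}

#' Adopted and marginal adopted area along a harvested-area path
#'
#' Applies an adoption curve to a per-year harvested-area path: before the
#' release year nothing is adopted; from the release year on the adopted area
#' is `A(t) * area(t)`. The marginal (newly adopted) area is the year-on-year
#' increase, clamped at zero — a shrinking total area never yields negative
#' dissemination ("dis-dissemination" refunds are not credited).
#'
#' @param curve A `pe_adoption`.
#' @param area_path Tibble with columns `year` and `area` (kha) covering the
#'   horizon.
#' @param release_year First year of adoption; must fall inside the path.
#' @return Tibble with `year`, `adopted` (kha) and `marginal` (kha).
#' @export
adopted_area_path <- function(curve, area_path, release_year) {
  stopifnot(all(c("year", "area") %in% names(area_path)))
  if (!release_year %in% area_path$year) {
    rlang::abort(sprintf("release year %s lies outside the horizon %s-%s",
                         release_year, min(area_path$year), max(area_path$year)))
  }
  out <- area_path |>
    dplyr::arrange(.data$year) |>
    dplyr::mutate(
      rate = ifelse(.data$year >= release_year,
                    adoption_rate(curve, .data$year), 0),
      adopted = .data$rate * .data$area,
      marginal = pmax(0, .data$adopted - dplyr::lag(.data$adopted, default = 0))) |>
    dplyr::select("year", "adopted", "marginal")
  out
}
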