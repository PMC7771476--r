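#' Assemble a world model
#'
#' A world model bundles everything the market simulator needs: the commodity
#' set (exactly one of which is the *focus* commodity whose market welfare is
#' measured), the regions with their target/non-target flag, the base-year
#' market calibration, the price-elasticity tables for area and demand
#' responses, and the simulation horizon. All quantities use fixed units:
#' harvested area in thousand hectares (kha), yields in t/ha, quantities in
#' thousand tonnes (kt), prices in US$/t, and money in million US$ at constant
#' prices.
#'
#' @param commodities Tibble with columns `commodity` (character) and
#'   `is_focus` (logical). Exactly one commodity must be flagged as focus.
#' @param regions Tibble with columns `region` (character) and `target`
#'   (logical) marking regions eligible for technology targeting.
#' @param calibration Tibble with one row per (region, commodity):
#'   `region`, `commodity`, `yield_base` (t/ha), `area_base` (kha),
#'   `price_base` (US$/t), `demand_base` (kt), `yield_price_elast` (own-price
#'   elasticity of yield, >= 0), `input_price_elast` (elasticity of yield with
#'   respect to the input-price index), `input_price_base` (exogenous
#'   input-price index, held at base by default), `income_elast` (income
#'   elasticity of food demand).
#' @param demographics Tibble with one row per region: `region`, `population`
#'   (millions), `income` (per-capita income index at base year).
#' @param area_elasticity Long tibble of area responses: `region`,
#'   `commodity`, `wrt` (the commodity whose price the response refers to),
#'   `elast`. Own-price entries (`wrt == commodity`) must be non-negative.
#' @param demand_elasticity Long tibble of demand responses, same layout.
#'   Own-price entries must be negative.
#' @param horizon Integer vector `c(first, last)` of simulation years,
#'   inclusive at both ends (the default study runs 2015-2040, 26 annual
#'   steps).
#'
#' @return An object of class `pe_world`.
#' @seealso [validate_world()], [generate_world()]
#' @export
world_model <- function(commodities, regions, calibration, demographics,
                        area_elasticity, demand_elasticity,
                        horizon = c(2015L, 2040L)) {
  world <- structure(
    list(
      commodities = tibble::as_tibble(commodities),
      regions = tibble::as_tibble(regions),
      calibration = tibble::as_tibble(calibration),
      demographics = tibble::as_tibble(demographics),
      area_elasticity = tibble::as_tibble(area_elasticity),
      demand_elasticity = tibble::as_tibble(demand_elasticity),
      horizon = as.integer(horizon)
    ),
    class = "pe_world"
  )
  problems <- validate_world(world)
  if (length(problems) > 0) {
    rlang::abort(c("invalid world model", problems))
  }
  world
}

#' Validate a world model
#'
#' Checks every structural invariant of a `pe_world`: unique identifiers, a
#' single focus commodity, strict positivity of prices, areas, yields,
#' population and demand, elasticity sign conventions (demand own-price
#' negative, supply-side own-price non-negative), a complete region x
#' commodity calibration grid, and base-year global market clearing per
#' commodity (global supply equals global demand within `tol` relative
#' error).
#'
#' Findings are returned rather than thrown so that callers can decide
#' whether a violation is fatal.
#'
#' @param world A `pe_world` (or a bare list with the same fields).
#' @param tol Relative tolerance for the base-year clearing check.
#' @return Character vector of violation descriptions; `character(0)` when
#'   all invariants hold.
#' @export
validate_world <- function(world, tol = 1e-6) {
  problems <- character()
  note <- function(msg) problems <<- c(problems, msg)

  cm <- world$commodities
  rg <- world$regions
  cal <- world$calibration

  if (anyDuplicated(cm$commodity)) note("commodity ids are not unique")
  if (sum(cm$is_focus) != 1L) {
    note(sprintf("exactly one focus commodity required, found %d",
                 sum(cm$is_focus)))
  }
  if (anyDuplicated(rg$region)) note("region ids are not unique")

  expected <- nrow(cm) * nrow(rg)
  key <- paste(cal$region, cal$commodity)
  if (nrow(cal) != expected || anyDuplicated(key)) {
    note(sprintf(
      "calibration must cover each region x commodity exactly once (%d rows, expected %d)",
      nrow(cal), expected))
  }

  check_pos <- function(df, col, label) {
    bad <- which(!is.finite(df[[col]]) | df[[col]] <= 0)
    for (i in utils::head(bad, 5)) {
      note(sprintf("%s must be strictly positive: %s/%s %s = %g",
                   label, df$region[i],
                   if ("commodity" %in% names(df)) df$commodity[i] else "",
                   col, df[[col]][i]))
    }
  }
  check_pos(cal, "yield_base", "base yield")
  check_pos(cal, "area_base", "base area")
  check_pos(cal, "price_base", "base price")
  check_pos(cal, "demand_base", "base demand")
  check_pos(cal, "input_price_base", "input price index")
  check_pos(world$demographics, "population", "population")
  check_pos(world$demographics, "income", "income index")

  bad_eps <- which(cal$yield_price_elast < 0)
  for (i in utils::head(bad_eps, 5)) {
    note(sprintf("yield own-price elasticity must be non-negative: %s/%s = %g",
                 cal$region[i], cal$commodity[i], cal$yield_price_elast[i]))
  }

  own_dem <- dplyr::filter(world$demand_elasticity, .data$wrt == .data$commodity)
  bad <- which(own_dem$elast >= 0)
  for (i in utils::head(bad, 5)) {
    note(sprintf("demand own-price elasticity must be negative: %s/%s = %g",
                 own_dem$region[i], own_dem$commodity[i], own_dem$elast[i]))
  }
  own_area <- dplyr::filter(world$area_elasticity, .data$wrt == .data$commodity)
  bad <- which(own_area$elast < 0)
  for (i in utils::head(bad, 5)) {
    note(sprintf("area own-price elasticity must be non-negative: %s/%s = %g",
                 own_area$region[i], own_area$commodity[i], own_area$elast[i]))
  }

  # base-year market clearing: global supply == global demand per commodity
  clr <- cal |>
    dplyr::group_by(.data$commodity) |>
    dplyr::summarise(
      supply = sum(.data$yield_base * .data$area_base),
      demand = sum(.data$demand_base), .groups = "drop") |>
    dplyr::mutate(residual = abs(.data$supply - .data$demand) / .data$demand)
  for (i in which(clr$residual > tol)) {
    note(sprintf(
      "base-year market does not clear for %s: supply %.6g kt vs demand %.6g kt",
      clr$commodity[i], clr$supply[i], clr$demand[i]))
  }

  if (length(world$horizon) != 2L || world$horizon[1] >= world$horizon[2]) {
    note("horizon must be two increasing years c(first, last)")
  }

  problems
}

#' @export
print.pe_world <- function(x, ...) {
  focus <- x$commodities$commodity[x$commodities$is_focus]
  cat(sprintf(
    "<pe_world> %d regions (%d target) x %d commodities (focus: %s), %d-%d\n",
    nrow(x$regions), sum(x$regions$target), nrow(x$commodities), focus,
    x$horizon[1], x$horizon[2]))
  invisible(x)
}

#' Focus commodity of a world
#' @param world A `pe_world`.
#' @return The focus commodity id (character scalar).
#' @export
focus_commodity <- function(world) {
  world$commodities$commodity[world$commodities$is_focus]
}

#' Simulation years of a world
#' @param world A `pe_world`.
#' @return Integer vector of calendar years covered by the horizon.
#' @export
world_years <- function(world) {
  seq.int(world$horizon[1], world$horizon[2])
}

# ---- configuration round trip ------------------------------------------

# doubles are written as %.17g strings so the YAML round trip is exact to
# the last ulp; the reader coerces every column back to its schema type
tbl_to_config <- function(df) {
  lapply(as.list(df), function(col) {
    if (is.factor(col)) col <- as.character(col)
    if (is.double(col)) col <- sprintf("%.17g", col)
    col
  })
}

config_to_tbl <- function(lst, types) {
  cols <- lapply(names(types), function(nm) {
    col <- lst[[nm]]
    switch(types[[nm]],
           character = as.character(col),
           double = as.numeric(col),
           integer = as.integer(col),
           logical = as.logical(col))
  })
  names(cols) <- names(types)
  tibble::as_tibble(cols)
}

world_schemas <- function() {
  list(
    commodities = c(commodity = "character", is_focus = "logical"),
    regions = c(region = "character", target = "logical"),
    calibration = c(region = "character", commodity = "character",
                    yield_base = "double", area_base = "double",
                    price_base = "double", demand_base = "double",
                    yield_price_elast = "double", input_price_elast = "double",
                    input_price_base = "double", income_elast = "double"),
    demographics = c(region = "character", population = "double",
                     income = "double"),
    area_elasticity = c(region = "character", commodity = "character",
                        wrt = "character", elast = "double"),
    demand_elasticity = c(region = "character", commodity = "character",
                          wrt = "character", elast = "double")
  )
}

#' Write a world model to a YAML configuration file
#'
#' The configuration is plain structured text (column lists per table) and
#' round-trips exactly: [read_world_config()] restores the world
#' field-by-field, including full double precision.
#'
#' @param world A `pe_world`.
#' @param path File path to write.
#' @return `path`, invisibly.
#' @export
write_world_config <- function(world, path) {
  doc <- list(
    world = c(
      lapply(world[names(world_schemas())], tbl_to_config),
      list(horizon = as.integer(world$horizon))
    )
  )
  writeLines(yaml::as.yaml(doc, precision = 17L), path)
  invisible(path)
}

#' Read a world model from a YAML configuration file
#'
#' @param path File written by [write_world_config()] (or hand-authored with
#'   the same schema).
#' @return A validated `pe_world`.
#' @export
read_world_config <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$world)) {
    rlang::abort("config error: missing top-level field 'world'")
  }
  w <- doc$world
  schemas <- world_schemas()
  for (nm in c(names(schemas), "horizon")) {
    if (is.null(w[[nm]])) {
      rlang::abort(sprintf("config error: missing field 'world.%s'", nm))
    }
  }
  tables <- lapply(names(schemas), function(nm) config_to_tbl(w[[nm]], schemas[[nm]]))
  names(tables) <- names(schemas)
  world_model(tables$commodities, tables$regions, tables$calibration,
              tables$demographics, tables$area_elasticity,
              tables$demand_elasticity, horizon = as.integer(w$horizon))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.pe_world <- function(x, ...) x$calibration

#' @export
glance.pe_world <- function(x, ...) {
  tibble::tibble(
    n_regions = nrow(x$regions),
    n_target = sum(x$regions$target),
    n_commodities = nrow(x$commodities),
    focus = focus_commodity(x),
    first_year = x$horizon[1],
    last_year = x$horizon[2]
  )
}
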