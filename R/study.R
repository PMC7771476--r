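#' Run a full priority-setting study grid
#'
#' Composes the whole pipeline for a technology x scenario grid: for each
#' pathway it generates scenario drivers, solves the no-shock baseline
#' trajectory, then for every technology builds the adoption/yield shock,
#' solves the shocked trajectory, and assembles the benefit-cost report for
#' both aggregations. Summary tables mirror the usual reporting layout:
#' production impacts (% change in yield, land and supply by country group in
#' the final year), world price impacts per commodity, and an adoption
#' summary (dissemination and total cost NPVs, final adopted area).
#'
#' @param world A `pe_world`.
#' @param technologies Named list of `pe_technology` objects.
#' @param pathways Character vector of scenario names (see
#'   [generate_drivers()]).
#' @param seed Seed forwarded to the driver generator.
#' @param discount_rate Discount rate for all NPVs.
#' @param a0_frac Initial adoption rate as a fraction of the ceiling.
#' @param tol Market-solver tolerance.
#' @return A list of class `pe_study` with elements `report` (one row per
#'   technology x pathway x aggregation), `production_impacts`,
#'   `price_impacts`, `adoption`, `trajectories`, and the run settings.
#' @export
run_priority_study <- function(world, technologies,
                               pathways = ssp_rcp_pathways(),
                               seed = 1L, discount_rate = 0.10,
                               a0_frac = 0.005, tol = 1e-8) {
  if (is.null(names(technologies))) {
    names(technologies) <- vapply(technologies, function(t) t$name, character(1))
  }
  focus <- focus_commodity(world)
  final_year <- world$horizon[2]

  reports <- list()
  prod_imp <- list()
  price_imp <- list()
  adoption <- list()
  trajectories <- list()

  for (pw in pathways) {
    drivers <- generate_drivers(pw, world, seed = seed)
    baseline <- run_scenario(world, drivers, tol = tol)
    trajectories[[pw]] <- list(baseline = baseline, shocked = list())
    for (nm in names(technologies)) {
      tech <- technologies[[nm]]
      shock <- build_shock(tech, world, drivers, a0_frac = a0_frac)
      shocked <- run_scenario(world, drivers, shock, tol = tol)
      trajectories[[pw]]$shocked[[nm]] <- shocked

      rep <- welfare_report(baseline, shocked, world, shock,
                            discount_rate = discount_rate) |>
        dplyr::mutate(pathway = pw, .after = "technology")
      reports[[paste(pw, nm)]] <- rep

      prod_imp[[paste(pw, nm)]] <-
        production_impacts(baseline, shocked, world, shock, final_year) |>
        dplyr::mutate(technology = nm, pathway = pw, .before = 1)

      price_imp[[paste(pw, nm)]] <-
        price_impacts(baseline, shocked, final_year) |>
        dplyr::mutate(technology = nm, pathway = pw, .before = 1)

      adopted <- marginal_adopted(shocked, world, shock)
      costs <- cost_stream(tech, adopted, world$horizon)
      adoption[[paste(pw, nm)]] <- tibble::tibble(
        technology = nm, pathway = pw,
        dissemination_cost_npv = npv(costs$dissemination_cost, discount_rate),
        total_cost_npv = npv(costs$cost, discount_rate),
        final_adopted_area = adopted$adopted[adopted$year == final_year])
    }
  }

  structure(
    list(report = purrr::list_rbind(unname(reports)),
         production_impacts = purrr::list_rbind(unname(prod_imp)),
         price_impacts = purrr::list_rbind(unname(price_imp)),
         adoption = purrr::list_rbind(unname(adoption)),
         trajectories = trajectories,
         world = world, pathways = pathways, seed = seed,
         discount_rate = discount_rate, focus = focus),
    class = "pe_study")
}

# Internal: % changes from baseline in the final year by country group
production_impacts <- function(baseline, shocked, world, shock, year) {
  focus <- focus_commodity(world)
  targets <- shock$tech$targets$region
  agg <- function(tr, grp_regions, label) {
    rows <- tr |>
      dplyr::filter(.data$commodity == focus, .data$year == !!year,
                    .data$region %in% grp_regions)
    tibble::tibble(group = label,
                   land = sum(rows$area),
                   supply = sum(rows$supply)) |>
      dplyr::mutate(yield = .data$supply / .data$land)
  }
  all_regions <- world$regions$region
  groups <- list(target = targets,
                 non_target = setdiff(all_regions, targets),
                 global = all_regions)
  out <- purrr::imap(groups, function(rg, label) {
    b <- agg(baseline, rg, label)
    s <- agg(shocked, rg, label)
    tibble::tibble(
      group = label,
      yield_pct = 100 * (s$yield / b$yield - 1),
      land_pct = 100 * (s$land / b$land - 1),
      supply_pct = 100 * (s$supply / b$supply - 1))
  })
  purrr::list_rbind(unname(out))
}

# Internal: % change in final-year world prices per commodity
price_impacts <- function(baseline, shocked, year) {
  b <- baseline |>
    dplyr::filter(.data$year == !!year) |>
    dplyr::distinct(.data$commodity, .data$world_price)
  s <- shocked |>
    dplyr::filter(.data$year == !!year) |>
    dplyr::distinct(.data$commodity, .data$world_price)
  dplyr::inner_join(b, s, by = "commodity", suffix = c("_base", "_shocked")) |>
    dplyr::mutate(price_pct = 100 * (.data$world_price_shocked /
                                       .data$world_price_base - 1)) |>
    dplyr::select("commodity", "price_pct")
}

#' @export
print.pe_study <- function(x, ...) {
  cat(sprintf(
    "<pe_study> %d technologies x %d scenarios (focus: %s, discount rate %.0f%%)\n",
    length(unique(x$report$technology)), length(x$pathways), x$focus,
    100 * x$discount_rate))
  invisible(x)
}

#' @export
tidy.pe_study <- function(x, ...) dplyr::select(x$report, -"stream")

#' @export
glance.pe_study <- function(x, ...) {
  top <- rank_technologies(x$report, "npv", aggregation = "all",
                           pathway = x$pathways[1])
  tibble::tibble(
    n_technologies = length(unique(x$report$technology)),
    n_pathways = length(x$pathways),
    focus = x$focus,
    discount_rate = x$discount_rate,
    top_technology = top$technology[1],
    top_net_npv = top$net_npv[1])
}

#' Compare target-only against all-countries net benefits
#'
#' For every technology x scenario, tabulates the net-benefit NPV under both
#' aggregations and their ratio (target / all). Ignoring non-target
#' countries overstates net benefits whenever the ratio exceeds one. The
#' ratio is left `NA` (flagged) when the all-countries NPV is zero, and rows
#' where the two aggregations disagree in sign are flagged.
#'
#' @param report A study report (`tidy()` of a `pe_study`, or the bound rows
#'   of several [welfare_report()] calls with a `pathway` column).
#' @return Tibble `technology`, `pathway`, `npv_target`, `npv_all`, `ratio`,
#'   `sign_flip`.
#' @export
compare_aggregations <- function(report) {
  if (inherits(report, "pe_study")) report <- tidy(report)
  have <- unique(report$aggregation)
  if (!all(c("all", "target") %in% have)) {
    rlang::abort(sprintf("both aggregations required, found: %s",
                         paste(have, collapse = ", ")))
  }
  keys <- intersect(c("technology", "pathway"), names(report))
  report |>
    dplyr::select(dplyr::all_of(keys), "aggregation", "net_npv") |>
    tidyr::pivot_wider(names_from = "aggregation", values_from = "net_npv") |>
    dplyr::rename(npv_all = "all", npv_target = "target") |>
    dplyr::mutate(
      ratio = ifelse(.data$npv_all == 0, NA_real_,
                     .data$npv_target / .data$npv_all),
      sign_flip = sign(.data$npv_target) != sign(.data$npv_all))
}

# ---- study configuration files -----------------------------------------

study_config_error <- function(field, msg) {
  rlang::abort(sprintf("config error in field '%s': %s", field, msg))
}

parse_study_config <- function(config) {
  if (is.null(config$study)) study_config_error("study", "missing section")
  st <- config$study
  pathways <- st$pathways %||% ssp_rcp_pathways()
  unknown <- setdiff(pathways, ssp_rcp_pathways())
  if (length(unknown) > 0) {
    study_config_error("study.pathways",
                       sprintf("unknown scenario name(s): %s",
                               paste(unknown, collapse = ", ")))
  }
  discount <- st$discount_rate %||% 0.10
  if (!is.numeric(discount) || discount <= -1) {
    study_config_error("study.discount_rate", "must be a number > -1")
  }
  seed <- st$seed %||% 1L
  if (!is.numeric(seed)) study_config_error("study.seed", "must be an integer")
  list(name = st$name %||% "study", pathways = pathways,
       discount_rate = discount, seed = as.integer(seed),
       technology_seed = as.integer(st$technology_seed %||% 1L),
       technologies = st$technologies %||% "potato_fixtures")
}

build_config_world <- function(config) {
  wc <- config$world
  if (is.null(wc)) study_config_error("world", "missing section")
  if (!is.null(wc$file)) return(read_world_config(wc$file))
  gen <- wc$generator %||% list()
  allowed <- setdiff(names(formals(generator_config)), "")
  unknown <- setdiff(names(gen), allowed)
  if (length(unknown) > 0) {
    study_config_error(paste0("world.generator.", unknown[1]),
                       "unknown generator setting")
  }
  seed <- gen$seed %||% config$study$seed %||% 1L
  gen$seed <- NULL
  generate_world(do.call(generator_config, gen), seed = as.integer(seed))
}

#' Run a study from a configuration file
#'
#' Reads a YAML study configuration, runs the full technology x scenario
#' grid, and writes all result tables, per-scenario baseline trajectories and
#' a reproducibility manifest to `out_dir`. Identical configuration and seed
#' produce byte-identical outputs.
#'
#' The configuration has two sections: `study` (`name`, `seed`,
#' `discount_rate`, `pathways`, `technologies` — currently the
#' `potato_fixtures` set — and `technology_seed`) and `world` (either
#' `file:` pointing to a [write_world_config()] document, or `generator:`
#' with [generator_config()] settings). Validation failures report the
#' offending field path.
#'
#' @param config_path Path to the YAML study configuration.
#' @param out_dir Output directory (created if needed).
#' @param seed Optional override of the configured seed.
#' @return The `pe_study`, invisibly, with the written file paths in
#'   attribute `paths`.
#' @export
run_study <- function(config_path, out_dir, seed = NULL) {
  if (!file.exists(config_path)) {
    rlang::abort(sprintf("config file not found: %s", config_path))
  }
  config <- yaml::read_yaml(config_path)
  st <- parse_study_config(config)
  if (!is.null(seed)) st$seed <- as.integer(seed)

  world <- build_config_world(config)
  if (identical(st$technologies, "potato_fixtures")) {
    technologies <- potato_technologies(world, seed = st$technology_seed)
  } else {
    study_config_error("study.technologies",
                       "only the 'potato_fixtures' set is supported")
  }

  study <- run_priority_study(world, technologies, pathways = st$pathways,
                              seed = st$seed,
                              discount_rate = st$discount_rate)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  emit <- function(df, name) {
    p <- file.path(out_dir, name)
    readr::write_csv(df, p)
    paths <<- c(paths, p)
  }
  emit(tidy(study), "welfare_report.csv")
  emit(compare_aggregations(study), "aggregation_comparison.csv")
  rankings <- purrr::list_rbind(purrr::map(st$pathways, function(pw) {
    purrr::list_rbind(purrr::map(c("all", "target"), function(agg) {
      rank_technologies(study$report, "npv", aggregation = agg, pathway = pw) |>
        dplyr::select("pathway", "aggregation", "technology", "net_npv", "rank")
    }))
  }))
  emit(rankings, "ranking.csv")
  emit(study$production_impacts, "production_impacts.csv")
  emit(study$price_impacts, "price_impacts.csv")
  emit(study$adoption, "adoption.csv")
  for (pw in st$pathways) {
    emit(tidy(study$trajectories[[pw]]$baseline),
         sprintf("trajectory_baseline_%s.csv", gsub("[^A-Za-z0-9.]+", "_", pw)))
  }

  manifest <- list(
    study = st$name,
    seed = st$seed,
    technology_seed = st$technology_seed,
    discount_rate = st$discount_rate,
    pathways = st$pathways,
    config_hash = rlang::hash(list(config, st$seed)),
    solver = list(tol = 1e-8, max_iter = 50L),
    package = as.character(utils::packageVersion("agsurplus")),
    files = basename(paths))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  paths <- c(paths, manifest_path)

  attr(study, "paths") <- paths
  invisible(study)
}
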