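#' Assessment configuration
#'
#' Collects every tunable constant of the pipeline with the framework's
#' standard values: dispersal kernel thresholds of 300 km under current
#' conditions, rising to 630 km (2055) and 1080 km (2085) — an expansion
#' allowance of 15 km per year between horizons; water traversal cost
#' twice land (100 times for the barrier scenario); exposure cuts of 2 SD
#' (single factor), 1 SD over >= 2 factors, and 10% of habitat within 1 m
#' of sea level; a sensitivity cut of 1; a 30-level threshold sweep with a
#' slope cut of -1; dispersal-pressure flagging at 3 of 5 points; and
#' roster cuts of 30 (modelled) / 15 (uncommon) subcatchments.
#'
#' @param ... Named overrides, nested lists merged into the defaults (e.g.
#'   `grid = list(n_rows = 20)`).
#' @return A list of class `vuln_config`.
#' @export
vuln_config <- function(...) {
  cfg <- list(
    seed = 1L,
    grid = list(
      n_rows = 50, n_cols = 50, cell_size = 25, n_subcatchments = 150,
      sea_fraction = 0.15, max_elev = 1500
    ),
    species = list(
      n_species = 30, n_records_range = c(80, 400), bias_strength = 2,
      n_bias_centers = 3, year_range = c(1990, 2013), niche_spread = list()
    ),
    scenarios = list(
      horizons = tibble(
        scenario = c("RCP8.5-2055", "RCP8.5-2085"),
        year = c(2055, 2085),
        kernel_threshold_km = c(630, 1080)
      )
    ),
    kernel = list(current_threshold = 300, b = 4, a = 1, c = 0),
    dispersal_rate_km_yr = 15,
    water_multiplier = 2,
    barrier_multiplier = 100,
    exposure = list(
      single_cut = 2, multi_cut = 1, multi_n = 2, sea_cut = 0.10, rise = 1,
      mapping = default_exposure_mapping()
    ),
    sensitivity_cut = 1,
    sweep = list(n_levels = 30, slope_cut = -1),
    pressure_cut = 3,
    roster = list(min_model = 30, min_uncommon = 15, removals = character()),
    pseudo_absences = list(radius_km = 300, n_total = 300),
    ensemble = list(n_replicates = 5, train_frac = 0.7)
  )
  over <- list(...)
  for (nm in names(over)) {
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(over[[nm]]) &&
      !is.data.frame(over[[nm]])) {
      modifyList(cfg[[nm]], over[[nm]])
    } else {
      over[[nm]]
    }
  }
  stopifnot(
    cfg$kernel$current_threshold > 0,
    all(diff(c(
      cfg$kernel$current_threshold,
      cfg$scenarios$horizons$kernel_threshold_km
    )) > 0),
    cfg$roster$min_uncommon < cfg$roster$min_model
  )
  structure(cfg, class = c("vuln_config", "list"))
}

#' Implied range-expansion rate between two horizons
#'
#' The kernel thresholds encode a dispersal allowance: the rate is the
#' threshold increase divided by the years elapsed between horizons.
#'
#' @param config A `vuln_config`.
#' @return Rate in km per year (scalar; computed from the last two
#'   horizons).
#' @export
implied_expansion_rate <- function(config) {
  h <- config$scenarios$horizons
  n <- nrow(h)
  stopifnot(n >= 2)
  (h$kernel_threshold_km[n] - h$kernel_threshold_km[n - 1]) /
    (h$year[n] - h$year[n - 1])
}

#' @export
print.vuln_config <- function(x, ...) {
  cat(sprintf(
    "<vuln_config> seed %d, %dx%d grid, %d species, scenarios: %s\n",
    x$seed, x$grid$n_rows, x$grid$n_cols, x$species$n_species,
    paste(x$scenarios$horizons$scenario, collapse = ", ")
  ))
  invisible(x)
}

config_hash <- function(config) {
  substr(rlang::hash(unclass(config)), 1, 12)
}
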