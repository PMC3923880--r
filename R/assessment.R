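#' Vulnerability category from the three component flags
#'
#' Exposed + sensitive + pressured = Category 1 (highly vulnerable);
#' exposed + sensitive = Category 2 (vulnerable in place); exposed +
#' pressured = Category 3 (potential to persist via dispersal); sensitive
#' + pressured = Category 4 (decline and shift before exposure). Every
#' other combination — at risk in at most one component — is "LC" (least
#' concern); the raw flags are always carried in the reports so users can
#' re-bin.
#'
#' @param exposed,sensitive,pressured Logical flags (vectorized).
#' @return Character vector in `{"1","2","3","4","LC"}`.
#' @export
assign_category <- function(exposed, sensitive, pressured) {
  stopifnot(length(exposed) == length(sensitive), length(exposed) == length(pressured))
  dplyr::case_when(
    exposed & sensitive & pressured ~ "1",
    exposed & sensitive & !pressured ~ "2",
    exposed & !sensitive & pressured ~ "3",
    !exposed & sensitive & pressured ~ "4",
    .default = "LC"
  )
}

#' Assess one species under one future scenario
#'
#' Runs the three vulnerability components and assigns the category:
#' exposure over the current dispersal-constrained habitat, sensitivity of
#' thresholded suitability totals, and dispersal pressure (habitat-shift
#' rank-sum score plus threshold-sweep score).
#'
#' @param species Species id.
#' @param current_surface Current dispersal-constrained
#'   `suitability_surface` (TSS threshold set).
#' @param future_surface Future dispersal-constrained
#'   `suitability_surface`.
#' @param future_unkerneled Future surface before dispersal weighting (for
#'   the threshold sweep).
#' @param current_stack,future_stack `scenario_stack`s.
#' @param distances The species' `distance_field`.
#' @param landscape A `vuln_landscape`.
#' @param config Assessment configuration, see [vuln_config()].
#' @param future_threshold Kernel threshold (km) for the scenario's
#'   horizon.
#' @return Object of class `vulnerability_record` with components
#'   `exposure`, `sensitivity`, `dispersal`, `category`; `tidy()` gives the
#'   one-row report.
#' @export
assess_species <- function(species, current_surface, future_surface,
                           future_unkerneled, current_stack, future_stack,
                           distances, landscape, config, future_threshold) {
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Assessment of %s failed at stage '%s': %s", species, what, conditionMessage(e)))
    })
  }
  cur_mask <- stage("binarize-current", binarize_surface(current_surface))
  cur_suit <- cur_mask$subcatchment[cur_mask$suitable]
  fut_mask <- stage("binarize-future", binarize_surface(future_surface))
  fut_suit <- fut_mask$subcatchment[fut_mask$suitable]

  exp_res <- stage("exposure", assess_exposure(
    current_stack, future_stack, cur_suit, landscape,
    mapping = config$exposure$mapping, rise = config$exposure$rise,
    single_cut = config$exposure$single_cut, multi_cut = config$exposure$multi_cut,
    multi_n = config$exposure$multi_n, sea_cut = config$exposure$sea_cut
  ))
  sens_res <- stage("sensitivity", sensitivity_weight(current_surface, future_surface))
  shift <- stage("habitat-shift", habitat_shift_score(cur_suit, fut_suit, distances))
  sweep <- stage("threshold-sweep", threshold_sweep(
    future_unkerneled, current_surface, distances,
    base_threshold = config$kernel$current_threshold,
    future_threshold = future_threshold,
    n_levels = config$sweep$n_levels, slope_cut = config$sweep$slope_cut,
    b = config$kernel$b
  ))
  disp <- dispersal_pressure(shift$score, sweep$sweep_score,
    shift_z = shift$z, slopes = sweep$slopes,
    pressure_cut = config$pressure_cut
  )
  structure(
    list(
      species = species,
      scenario = attr(future_surface, "scenario"),
      exposure = exp_res, sensitivity = sens_res, dispersal = disp,
      category = assign_category(exp_res$exposed, sens_res$sensitive, disp$pressured)
    ),
    class = "vulnerability_record"
  )
}

#' @method tidy vulnerability_record
#' @export
tidy.vulnerability_record <- function(x, ...) {
  bind_cols(
    tibble(species = x$species, scenario = x$scenario),
    tibble(
      exposed = x$exposure$exposed,
      exposure_reasons = paste(x$exposure$reasons, collapse = ";"),
      sea_fraction = x$exposure$sea_fraction
    ),
    tidy(x$sensitivity),
    tidy(x$dispersal),
    tibble(category = x$category)
  )
}

#' Filter the species roster by occupied-subcatchment counts
#'
#' Species in 30 or more subcatchments are modelled normally; 15-29 are
#' modelled as "uncommon"; fewer are excluded. A removal list (species
#' dropped after modelling, e.g. for unstable projections) is applied
#' last; removed species are excluded whatever their counts.
#'
#' @param record_counts Tibble (species, n_subcatchments) or named vector.
#' @param min_model Modelled cut (default 30).
#' @param min_uncommon Uncommon cut (default 15; must be < `min_model`).
#' @param removals Character vector of species ids to drop.
#' @return Tibble: species, n_subcatchments, status ("modelled",
#'   "uncommon", "excluded"), removed, assessed.
#' @export
filter_roster <- function(record_counts, min_model = 30, min_uncommon = 15,
                          removals = character()) {
  stopifnot(min_uncommon < min_model)
  if (!is.data.frame(record_counts)) {
    record_counts <- tibble(
      species = names(record_counts),
      n_subcatchments = unname(record_counts)
    )
  }
  stopifnot(all(record_counts$n_subcatchments >= 0))
  unknown <- setdiff(removals, record_counts$species)
  if (length(unknown)) {
    warn(paste0(
      "Removal id(s) not in roster: ",
      paste(unknown, collapse = ", ")
    ))
  }
  record_counts |>
    mutate(
      status = dplyr::case_when(
        .data$species %in% removals ~ "excluded",
        .data$n_subcatchments >= min_model ~ "modelled",
        .data$n_subcatchments >= min_uncommon ~ "uncommon",
        .default = "excluded"
      ),
      removed = .data$species %in% removals,
      assessed = .data$status %in% c("modelled", "uncommon")
    )
}

#' Species whose sensitivity or category changed under a barrier scenario
#'
#' Compares vulnerability reports from the base run against a rerun with
#' the open-water traversal cost raised (the dispersal-barrier scenario)
#' and lists the species whose sensitive flag or category switched, with
#' the change in S.
#'
#' @param records_base,records_barrier Tidied vulnerability report tibbles
#'   (same species and scenario sets).
#' @return Tibble: species, scenario, S_base, S_barrier, delta_S,
#'   sensitive_base, sensitive_barrier, category_base, category_barrier.
#' @export
barrier_impact <- function(records_base, records_barrier) {
  key <- c("species", "scenario")
  if (!setequal(
    do.call(paste, records_base[key]),
    do.call(paste, records_barrier[key])
  )) {
    abort("Base and barrier runs cover different species/scenario rosters.")
  }
  inner_join(
    records_base |> select(all_of(key),
      S_base = "S",
      sensitive_base = "sensitive", category_base = "category"
    ),
    records_barrier |> select(all_of(key),
      S_barrier = "S",
      sensitive_barrier = "sensitive", category_barrier = "category"
    ),
    by = key
  ) |>
    mutate(delta_S = .data$S_barrier - .data$S_base) |>
    filter(.data$sensitive_base != .data$sensitive_barrier |
      .data$category_base != .data$category_barrier)
}

#' Sensitivity-weighted conservation priority map
#'
#' For the species in the selected vulnerability categories, each
#' subcatchment scores the sum over species of
#' `max(S, 0) * suitability` with suitability below the species' TSS
#' threshold zeroed (consistent with the sensitivity stage). Negative S
#' (expanding species) is clamped to zero here only, so expansion never
#' subtracts priority. Species that lost all future habitat (degenerate S)
#' contribute nothing to a future-scenario map and are skipped.
#'
#' @param surfaces Named list (species -> `suitability_surface`) for one
#'   scenario.
#' @param records Tidied vulnerability report tibble with species, S,
#'   category.
#' @param categories Categories included (default `c("1", "2")`).
#' @return Object of class `priority_map`: tibble (subcatchment, priority)
#'   with scenario/categories attributes.
#' @export
conservation_priority <- function(surfaces, records, categories = c("1", "2")) {
  keep <- records |>
    filter(.data$category %in% categories, !is.na(.data$S))
  missing <- setdiff(keep$species, names(surfaces))
  if (length(missing)) {
    abort(paste0(
      "No surface supplied for species: ",
      paste(missing, collapse = ", ")
    ))
  }
  base <- surfaces[[1]]
  score <- setNames(rep(0, nrow(base)), base$subcatchment)
  scenario <- NA_character_
  for (i in seq_len(nrow(keep))) {
    s <- keep$species[i]
    surf <- surfaces[[s]]
    scenario <- attr(surf, "scenario")
    tau <- attr(surf, "tss_threshold")
    v <- ifelse(surf$suitability >= tau, surf$suitability, 0)
    score[surf$subcatchment] <- score[surf$subcatchment] + max(keep$S[i], 0) * v
  }
  structure(
    tibble(subcatchment = names(score), priority = unname(score)),
    scenario = scenario, categories = categories,
    class = c("priority_map", class(tibble()))
  )
}
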