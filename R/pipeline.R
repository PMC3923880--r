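#' Run the full synthetic vulnerability-assessment pipeline
#'
#' Generates a landscape and scenario stacks, samples biased occurrence
#' records for synthetic species, filters the roster, fits a TSS-weighted
#' ensemble per species, projects and clamps suitability for every
#' scenario, constrains it by least-cost dispersal kernels, scores
#' exposure, sensitivity and dispersal pressure, assigns vulnerability
#' categories, reruns sensitivity and categories under the open-water
#' barrier scenario, and builds conservation priority maps. All randomness
#' flows from `config$seed`; reruns with the same config are byte-identical.
#'
#' @param config A [vuln_config()].
#' @param outdir Output directory for the report CSVs (optional; no files
#'   are written when `NULL`). Every file carries a `#` header with the
#'   config hash and seed.
#' @param quiet Suppress per-stage log lines.
#' @return Invisibly, a list: landscape, stacks, occurrences, roster,
#'   evaluations, surfaces (per species: list of kerneled/unkerneled per
#'   scenario), distances, records (tidied vulnerability report), records_barrier,
#'   barrier (changed species), priority (per-scenario `priority_map`s),
#'   files (paths written).
#' @export
run_pipeline <- function(config = vuln_config(), outdir = NULL, quiet = FALSE) {
  say <- function(...) if (!quiet) inform(sprintf(...))
  seed <- config$seed
  hdr <- c(
    paste("config", config_hash(config)),
    paste("seed", seed)
  )
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", what, conditionMessage(e)))
    })
  }

  g <- config$grid
  landscape <- stage("generate-landscape", generate_landscape(
    g$n_rows, g$n_cols, g$n_subcatchments,
    cell_size = g$cell_size,
    sea_fraction = g$sea_fraction, max_elev = g$max_elev,
    seed = derive_seed(seed, 1)
  ))
  say(
    "landscape: %d land cells in %d subcatchments (%d region(s))",
    sum(!landscape$cells$is_water), nrow(landscape$subcatchments),
    length(unique(landscape$subcatchments$region))
  )

  stacks <- stage("generate-scenarios", generate_scenarios(
    landscape,
    seed = derive_seed(seed, 2)
  ))
  future_names <- setdiff(names(stacks), "current")
  say("scenarios: current + %s", paste(future_names, collapse = ", "))
  say(
    "kernel thresholds: current %g km, future %s km (implied expansion %g km/yr)",
    config$kernel$current_threshold,
    paste(config$scenarios$horizons$kernel_threshold_km, collapse = "/"),
    implied_expansion_rate(config)
  )

  sp <- config$species
  niches <- stage("species-truth", generate_species_truth(
    sp$n_species, stacks$current,
    niche_spread = sp$niche_spread,
    seed = derive_seed(seed, 3)
  ))
  species_ids <- unique(niches$species)
  occurrences <- stage("sample-occurrences", {
    withr::with_seed(derive_seed(seed, 4), {
      n_rec <- sample(seq(sp$n_records_range[1], sp$n_records_range[2]),
        length(species_ids),
        replace = TRUE
      )
    })
    map(seq_along(species_ids), function(i) {
      sample_occurrences(
        niches |> filter(.data$species == species_ids[i]),
        landscape, stacks$current, n_rec[i],
        bias_strength = sp$bias_strength, n_bias_centers = sp$n_bias_centers,
        year_range = sp$year_range, seed = derive_seed(seed, 100 + i)
      )
    }) |> bind_rows()
  })
  say("occurrences: %d records for %d species", nrow(occurrences), length(species_ids))

  counts <- occurrences |>
    group_by(.data$species) |>
    summarise(n_subcatchments = n_distinct(.data$subcatchment), .groups = "drop")
  roster <- stage("filter-roster", filter_roster(
    counts,
    min_model = config$roster$min_model,
    min_uncommon = config$roster$min_uncommon,
    removals = config$roster$removals
  ))
  assessed <- roster$species[roster$assessed]
  if (length(assessed) == 0) {
    abort("Pipeline stage 'filter-roster' failed: no species passes the roster cuts; lower them or sample more records.")
  }
  say(
    "roster: %d modelled, %d uncommon, %d excluded -> %d assessed",
    sum(roster$status == "modelled"), sum(roster$status == "uncommon"),
    sum(roster$status == "excluded"), length(assessed)
  )

  cost_base <- build_cost_surface(landscape, config$water_multiplier)
  cost_barrier <- build_cost_surface(landscape, config$barrier_multiplier)
  horizons <- config$scenarios$horizons
  kp <- function(d0) kernel_params(d0, b = config$kernel$b, a = config$kernel$a, c = config$kernel$c)
  d0_of <- setNames(horizons$kernel_threshold_km, horizons$scenario)

  evaluations <- list()
  surfaces <- list()
  distances <- list()
  distances_barrier <- list()
  records <- list()
  records_barrier <- list()
  dropped <- character(0)

  for (i in seq_along(assessed)) {
    s <- assessed[i]
    occ_s <- occurrences |> filter(.data$species == s)
    presences <- occ_s |> distinct(.data$subcatchment, .keep_all = TRUE)
    pa <- stage(paste0("pseudo-absences:", s), select_pseudo_absences(
      occ_s, occurrences, landscape,
      n_total = config$pseudo_absences$n_total,
      radius_km = config$pseudo_absences$radius_km,
      seed = derive_seed(seed, 200 + i)
    ))
    ens <- stage(paste0("fit-ensemble:", s), fit_ensemble(
      presences, pa, stacks$current,
      n_replicates = config$ensemble$n_replicates,
      train_frac = config$ensemble$train_frac,
      seed = derive_seed(seed, 300 + i)
    ))
    evaluations[[s]] <- ens$evaluations |> mutate(species = s, .before = 1)
    tau <- stage(paste0("threshold:", s), ensemble_threshold(ens, presences, pa, stacks$current))
    limits <- ensemble_limits(ens)

    src <- unique(occ_s$cell)
    distances[[s]] <- stage(
      paste0("cost-distance:", s),
      cost_distance(cost_base, src, landscape, species = s)
    )
    distances_barrier[[s]] <- cost_distance(cost_barrier, src, landscape, species = s)

    per_scn <- list()
    for (scn in names(stacks)) {
      proj <- ensemble_project(ens, stacks[[scn]], species = s, tss_threshold = tau)
      unk <- clamp_surface(proj, stacks[[scn]], limits)
      d0 <- if (scn == "current") config$kernel$current_threshold else d0_of[[scn]]
      per_scn[[scn]] <- list(
        unkerneled = unk,
        kerneled = apply_kernel(unk, distances[[s]], kp(d0)),
        kerneled_barrier = apply_kernel(unk, distances_barrier[[s]], kp(d0))
      )
    }
    surfaces[[s]] <- per_scn

    cur_mask <- binarize_surface(per_scn$current$kerneled)
    if (!any(cur_mask$suitable)) {
      dropped <- c(dropped, s)
      next
    }
    for (scn in future_names) {
      rec <- stage(paste0("assess:", s, ":", scn), assess_species(
        s, per_scn$current$kerneled, per_scn[[scn]]$kerneled,
        per_scn[[scn]]$unkerneled, stacks$current, stacks[[scn]],
        distances[[s]], landscape, config, d0_of[[scn]]
      ))
      records[[paste(s, scn)]] <- rec
      if (any(binarize_surface(per_scn$current$kerneled_barrier)$suitable)) {
        recb <- stage(paste0("assess-barrier:", s, ":", scn), assess_species(
          s, per_scn$current$kerneled_barrier, per_scn[[scn]]$kerneled_barrier,
          per_scn[[scn]]$unkerneled, stacks$current, stacks[[scn]],
          distances_barrier[[s]], landscape, config, d0_of[[scn]]
        ))
      } else {
        recb <- rec
      }
      records_barrier[[paste(s, scn)]] <- recb
    }
  }
  if (length(dropped)) {
    say(
      "dropped %d species with no current habitat above threshold: %s",
      length(dropped), paste(dropped, collapse = ", ")
    )
    roster$status[roster$species %in% dropped] <- "excluded"
    roster$assessed[roster$species %in% dropped] <- FALSE
  }

  if (length(records) == 0) {
    abort("Pipeline stage 'assess' failed: no species retained current habitat above its threshold.")
  }
  report <- map(records, tidy) |> bind_rows()
  report_barrier <- map(records_barrier, tidy) |> bind_rows()
  say(
    "assessed %d species x %d scenarios; categories: %s",
    length(unique(report$species)), length(future_names),
    paste(names(table(report$category)), table(report$category),
      sep = "=", collapse = " "
    )
  )

  barrier <- stage("barrier-impact", barrier_impact(report, report_barrier))
  say("barrier scenario changed %d species x scenario entries", nrow(barrier))

  priority <- map(setNames(future_names, future_names), function(scn) {
    surf <- map(surfaces[unique(report$species)], function(p) p[[scn]]$kerneled)
    conservation_priority(surf, report |> filter(.data$scenario == scn))
  })
  say(
    "priority maps: %s subcatchments scored per scenario",
    paste(map_dbl(priority, nrow), collapse = "/")
  )

  files <- character(0)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    exposure_tbl <- map(records, function(r) {
      tidy(r$exposure) |> mutate(species = r$species, scenario = r$scenario, .before = 1)
    }) |> bind_rows()
    sensitivity_tbl <- map(records, function(r) {
      tidy(r$sensitivity) |> mutate(species = r$species, scenario = r$scenario, .before = 1)
    }) |> bind_rows()
    dispersal_tbl <- map(records, function(r) {
      tidy(r$dispersal) |> mutate(species = r$species, scenario = r$scenario, .before = 1)
    }) |> bind_rows()
    priority_tbl <- imap(priority, function(p, scn) {
      as_tibble(p) |> mutate(scenario = scn, .before = 1)
    }) |> bind_rows()
    out <- list(
      evaluation = bind_rows(evaluations),
      exposure = exposure_tbl,
      sensitivity = sensitivity_tbl,
      dispersal = dispersal_tbl,
      vulnerability = report,
      barrier_impact = barrier,
      priority = priority_tbl
    )
    files <- vapply(names(out), function(nm) {
      write_report(out[[nm]], file.path(outdir, paste0(nm, ".csv")), hdr)
    }, character(1))
    say("wrote %d report files to %s", length(files), outdir)
  }

  invisible(list(
    config = config, landscape = landscape, stacks = stacks, niches = niches,
    occurrences = occurrences, roster = roster,
    evaluations = bind_rows(evaluations), surfaces = surfaces,
    distances = distances, records = records, report = report,
    report_barrier = report_barrier, barrier = barrier, priority = priority,
    files = files
  ))
}
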