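#' Default baseline parameters for the seven environmental factors
#'
#' Three temperature factors (annual mean, seasonality, minimum of the
#' coldest month), three precipitation factors (wettest quarter, driest
#' quarter, seasonality) and one hydrological factor (mean annual flow).
#' Each per-subcatchment baseline value is
#' `mean + gradient_x * (x - x_mid) + gradient_y * (y - y_mid) + noise`,
#' with gradients per km so factors carry distinct, partly independent
#' spatial structure (temperature trends north-south, precipitation mostly
#' east-west).
#'
#' @return Tibble with columns factor, mean, gradient_x, gradient_y,
#'   noise_sd.
#' @export
default_factor_params <- function() {
  tibble(
    factor = VULN_FACTORS,
    mean = c(22, 1.2, 8, 400, 80, 0.9, 150),
    gradient_x = c(0, 0, 0, -0.25, -0.05, 0.0010, 0.04),
    gradient_y = c(-0.0075, 0.0008, -0.009, 0, 0.04, 0, 0.10),
    noise_sd = c(0.8, 0.12, 1.0, 45, 18, 0.10, 28)
  )
}

#' Default future-scenario anomalies
#'
#' Additive per-subcatchment anomalies for two future horizons under a high
#' emissions pathway: warming of roughly +1.8 degC by 2055 and +3.6 degC by
#' 2085 with drying precipitation and declining flow, each anomaly sampled
#' per subcatchment around the stated mean.
#'
#' @return Tibble with columns scenario, factor, mean, sd.
#' @export
default_anomalies <- function() {
  bind_rows(
    tibble(
      scenario = "RCP8.5-2055", factor = VULN_FACTORS,
      mean = c(1.8, 0.06, 1.8, -40, -12, 0.05, -20),
      sd = c(0.35, 0.02, 0.45, 16, 6, 0.02, 9)
    ),
    tibble(
      scenario = "RCP8.5-2085", factor = VULN_FACTORS,
      mean = c(3.6, 0.12, 3.6, -80, -24, 0.10, -40),
      sd = c(0.7, 0.04, 0.9, 32, 12, 0.04, 18)
    )
  )
}

#' Generate current and future environmental scenario stacks
#'
#' Builds the current per-subcatchment factor table from baseline
#' parameters, then one future stack per named scenario by adding a sampled
#' anomaly field (future = current + Normal(mean, sd) per subcatchment).
#' Only the additive anomaly structure of downscaled climate projections is
#' emulated.
#'
#' @param landscape A `vuln_landscape`.
#' @param baseline_params Tibble as [default_factor_params()]; must cover
#'   all seven factors.
#' @param anomalies Tibble as [default_anomalies()]; zero rows gives a
#'   current-only study.
#' @param seed Integer seed.
#' @return Named list of scenario stacks (`"current"` first). Each stack is
#'   a wide tibble (subcatchment + one column per factor) of class
#'   `scenario_stack` with a `scenario` attribute.
#' @export
generate_scenarios <- function(landscape, baseline_params = default_factor_params(),
                               anomalies = default_anomalies(), seed = 1) {
  missing <- setdiff(VULN_FACTORS, baseline_params$factor)
  if (length(missing)) {
    abort(paste0(
      "baseline_params is missing factor(s): ",
      paste(missing, collapse = ", ")
    ))
  }
  if (nrow(anomalies)) {
    bad <- anomalies |>
      count(.data$scenario) |>
      filter(.data$n != length(VULN_FACTORS))
    miss2 <- setdiff(unique(paste(anomalies$factor)), VULN_FACTORS)
    if (nrow(bad) || length(miss2)) {
      abort("Every future scenario must supply an anomaly for every factor.")
    }
  }
  sc <- landscape$subcatchments
  x_mid <- mean(range(landscape$cells$x))
  y_mid <- mean(range(landscape$cells$y))
  withr::with_seed(seed, {
    current <- sc |> select("subcatchment")
    for (i in seq_len(nrow(baseline_params))) {
      p <- baseline_params[i, ]
      v <- p$mean + p$gradient_x * (sc$x - x_mid) + p$gradient_y * (sc$y - y_mid) +
        rnorm(nrow(sc), 0, p$noise_sd)
      if (p$factor %in% c("p_wet", "p_dry", "flow")) v <- pmax(v, 0)
      current[[p$factor]] <- v
    }
    stacks <- list(current = new_scenario_stack(current, "current"))
    for (scn in unique(anomalies$scenario)) {
      fut <- current
      for (f in VULN_FACTORS) {
        a <- anomalies[anomalies$scenario == scn & anomalies$factor == f, ]
        shift <- if (a$sd > 0) rnorm(nrow(sc), a$mean, a$sd) else rep(a$mean, nrow(sc))
        fut[[f]] <- current[[f]] + shift
      }
      stacks[[scn]] <- new_scenario_stack(fut, scn)
    }
    stacks
  })
}

new_scenario_stack <- function(tbl, scenario) {
  structure(as_tibble(tbl), scenario = scenario, class = c("scenario_stack", class(tbl)))
}

#' Generate synthetic species with known Gaussian niches
#'
#' Each species gets, per factor, an optimum drawn uniformly between
#' quantiles of the realized current values and a tolerance expressed as a
#' multiple of the factor's spatial standard deviation, plus a peak
#' occupancy probability. Occupancy at a subcatchment is
#' `peak * prod_f exp(-0.5 * ((value_f - optimum_f) / tolerance_f)^2)`,
#' i.e. each factor's Gaussian is scaled to 1 at its optimum.
#'
#' @param n_species Number of species.
#' @param current_stack Current `scenario_stack`.
#' @param niche_spread List of hyperparameters: `optimum_quantiles` (range
#'   the optima are drawn from, default `c(0.1, 0.9)`), `tolerance_range`
#'   (multiples of the factor SD, default `c(0.4, 1.0)` — regionally
#'   restricted ranges rather than continental ones), `peak_range`
#'   (default `c(0.7, 0.95)`).
#' @param seed Integer seed.
#' @return Tibble of class `species_niche_set`, one row per species x
#'   factor: species, factor, optimum, tolerance, peak.
#' @export
generate_species_truth <- function(n_species, current_stack,
                                   niche_spread = list(), seed = 1) {
  stopifnot(n_species >= 1)
  hp <- modifyList(
    list(
      optimum_quantiles = c(0.1, 0.9),
      tolerance_range = c(0.4, 1.0),
      peak_range = c(0.7, 0.95)
    ),
    niche_spread
  )
  withr::with_seed(seed, {
    out <- vector("list", n_species)
    for (s in seq_len(n_species)) {
      sp <- sprintf("sp%03d", s)
      peak <- runif(1, hp$peak_range[1], hp$peak_range[2])
      rows <- map(VULN_FACTORS, function(f) {
        v <- current_stack[[f]]
        qs <- quantile(v, hp$optimum_quantiles, names = FALSE)
        tibble(
          species = sp, factor = f,
          optimum = runif(1, qs[1], qs[2]),
          tolerance = runif(1, hp$tolerance_range[1], hp$tolerance_range[2]) *
            max(sd(v), 1e-8),
          peak = peak
        )
      })
      out[[s]] <- bind_rows(rows)
    }
    structure(bind_rows(out),
      class = c("species_niche_set", class(tibble()))
    )
  })
}

#' True occupancy probability of synthetic species
#'
#' Evaluates the generating niche model on a scenario stack.
#'
#' @param niches A `species_niche_set` (one or more species).
#' @param stack A `scenario_stack`.
#' @return Tibble: species, subcatchment, occupancy.
#' @export
occupancy_probability <- function(niches, stack) {
  long <- stack |>
    tidyr::pivot_longer(all_of(intersect(VULN_FACTORS, names(stack))),
      names_to = "factor", values_to = "value"
    )
  niches |>
    inner_join(long, by = "factor", relationship = "many-to-many") |>
    group_by(.data$species, .data$subcatchment) |>
    summarise(
      occupancy = first(.data$peak) *
        exp(-0.5 * sum(((.data$value - .data$optimum) / .data$tolerance)^2)),
      .groups = "drop"
    )
}

#' Sample spatially biased occurrence records for one species
#'
#' Records are drawn over land cells with probability proportional to the
#' species' true occupancy of the cell's subcatchment times a spatial bias
#' factor `exp(-bias_strength * d / d_scale)`, where `d` is the distance to
#' the nearest of a few random bias centers (emulating collection effort
#' concentrated near settlements) and `d_scale` is the landscape diagonal.
#' `bias_strength = 0` gives unbiased, occupancy-proportional sampling.
#'
#' @param niche `species_niche_set` rows for a single species.
#' @param landscape A `vuln_landscape`.
#' @param current_stack Current `scenario_stack`.
#' @param n_records Number of records to draw (with replacement).
#' @param bias_strength Non-negative; larger concentrates sampling harder.
#' @param n_bias_centers Number of bias centers (default 3).
#' @param year_range Sampling window for record years.
#' @param seed Integer seed.
#' @return Tibble of class `occurrence_set`: species, cell, x, y,
#'   subcatchment, year, stage, sex. All records lie on land cells.
#' @export
sample_occurrences <- function(niche, landscape, current_stack, n_records,
                               bias_strength = 0, n_bias_centers = 3,
                               year_range = c(1990, 2013), seed = 1) {
  stopifnot(n_records >= 0, bias_strength >= 0)
  species <- unique(niche$species)
  stopifnot(length(species) == 1L)
  empty <- tibble(
    species = character(), cell = integer(), x = numeric(), y = numeric(),
    subcatchment = character(), year = integer(),
    stage = character(), sex = character()
  )
  if (n_records == 0L) {
    return(structure(empty, class = c("occurrence_set", class(empty))))
  }
  occ <- occupancy_probability(niche, current_stack)
  land <- landscape$cells |> filter(!.data$is_water)
  land <- land |> left_join(occ, by = "subcatchment")
  withr::with_seed(seed, {
    w <- land$occupancy
    w[is.na(w)] <- 0
    if (bias_strength > 0) {
      centers <- land[sample.int(nrow(land), n_bias_centers), c("x", "y")]
      d <- do.call(pmin, lapply(seq_len(nrow(centers)), function(i) {
        sqrt((land$x - centers$x[i])^2 + (land$y - centers$y[i])^2)
      }))
      d_scale <- sqrt((landscape$n_rows^2 + landscape$n_cols^2)) *
        landscape$cell_size
      w <- w * exp(-bias_strength * d / d_scale)
    }
    if (sum(w) <= 0) {
      abort(sprintf("Species %s has zero occupancy everywhere; cannot sample records.", species))
    }
    idx <- sample.int(nrow(land), n_records, replace = TRUE, prob = w)
    out <- tibble(
      species = species,
      cell = land$cell[idx], x = land$x[idx], y = land$y[idx],
      subcatchment = land$subcatchment[idx],
      year = sample(seq(year_range[1], year_range[2]), n_records, replace = TRUE),
      stage = sample(c("adult", "larva"), n_records, replace = TRUE),
      sex = sample(c("F", "M"), n_records, replace = TRUE)
    )
    structure(out, class = c("occurrence_set", class(out)))
  })
}
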