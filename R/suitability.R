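#' Aggregate per-cell values to subcatchment means
#'
#' @param cell_values Numeric vector aligned with `landscape$cells` rows
#'   (one value per cell; water cells may be NA).
#' @param landscape A `vuln_landscape`.
#' @return Tibble: subcatchment, value (arithmetic mean of member cells).
#' @export
aggregate_to_subcatchments <- function(cell_values, landscape) {
  cells <- landscape$cells
  stopifnot(length(cell_values) == nrow(cells))
  tbl <- tibble(
    subcatchment = cells$subcatchment,
    value = as.numeric(cell_values)
  ) |>
    filter(!is.na(.data$subcatchment))
  if (anyNA(tbl$value)) {
    bad <- tbl |>
      group_by(.data$subcatchment) |>
      summarise(ok = any(!is.na(.data$value)), .groups = "drop") |>
      filter(!.data$ok)
    if (nrow(bad)) {
      abort(paste0(
        "Subcatchment(s) with no valued cells: ",
        paste(bad$subcatchment, collapse = ", ")
      ))
    }
  }
  tbl |>
    group_by(.data$subcatchment) |>
    summarise(value = mean(.data$value, na.rm = TRUE), .groups = "drop")
}

#' Select pseudo-absence localities for one species
#'
#' Background localities (where other species were collected) lying within
#' `radius_km` of any presence record, and not sharing a subcatchment with
#' a presence, form the eligible pool; it is sampled first, and supplemented
#' where necessary by random subcatchment centroids from the remaining
#' landscape to reach `n_total`.
#'
#' @param target_occ Presence records for the focal species (tibble with
#'   x, y, subcatchment).
#' @param background Tibble of localities of other species (x, y,
#'   subcatchment; a `species` column, if present, is used to drop the
#'   focal species' own rows).
#' @param landscape A `vuln_landscape` (source of random supplements).
#' @param n_total Total number of pseudo-absences required.
#' @param radius_km Eligibility radius around presences (default 300 km).
#' @param seed Integer seed.
#' @return Tibble: x, y, subcatchment, source ("background" or "random").
#' @export
select_pseudo_absences <- function(target_occ, background, landscape, n_total,
                                   radius_km = 300, seed = 1) {
  stopifnot(n_total >= 1, nrow(background) > 0, nrow(target_occ) > 0)
  if ("species" %in% names(background) && "species" %in% names(target_occ)) {
    background <- background |> filter(!.data$species %in% unique(target_occ$species))
  }
  background <- background |> distinct(.data$x, .data$y, .data$subcatchment)
  pres_sub <- unique(target_occ$subcatchment)
  dmin <- min_dist_to(background$x, background$y, target_occ$x, target_occ$y)
  eligible <- background |>
    mutate(dmin = dmin) |>
    filter(.data$dmin <= radius_km, !.data$subcatchment %in% pres_sub) |>
    select(-"dmin")
  withr::with_seed(seed, {
    if (nrow(eligible) >= n_total) {
      out <- eligible[sample.int(nrow(eligible), n_total), ]
      out$source <- "background"
      return(out)
    }
    out <- eligible
    out$source <- if (nrow(out)) "background" else character(0)
    need <- n_total - nrow(out)
    pool <- landscape$cells |>
      filter(!.data$is_water, !.data$subcatchment %in% pres_sub) |>
      select("x", "y", "subcatchment") |>
      anti_join(eligible, by = c("x", "y"))
    if (nrow(pool) < need) {
      abort(sprintf(
        "Requested %d pseudo-absences but only %d candidates available.",
        n_total, nrow(eligible) + nrow(pool)
      ))
    }
    supp <- pool[sample.int(nrow(pool), need), ]
    supp$source <- "random"
    bind_rows(out, supp)
  })
}

## min Euclidean distance from each (x, y) to any of (px, py); chunked so the
## cross-distance matrix stays small.
min_dist_to <- function(x, y, px, py) {
  n <- length(x)
  out <- numeric(n)
  step <- 2000L
  for (i0 in seq(1L, n, by = step)) {
    i <- i0:min(i0 + step - 1L, n)
    m <- outer(x[i], px, "-")^2 + outer(y[i], py, "-")^2
    out[i] <- sqrt(apply(m, 1L, min))
  }
  out
}

#' Fit the built-in Gaussian-niche suitability scorer
#'
#' The built-in scorer is a binomial GLM on presence/absence labels with a
#' linear and quadratic term per factor (a Gaussian niche on the logit
#' scale), fitted by maximum likelihood. Factors are standardized
#' internally; factors with zero variance in the training data are dropped
#' with a warning. Training limits (per-factor min/max over training
#' localities) are recorded for environmental clamping.
#'
#' @param presences,absences Locality tibbles with a `subcatchment` column.
#' @param env A `scenario_stack` supplying factor values.
#' @param model_kind Label stored on the model (default
#'   `"gaussian_logistic"`). Alternative scorers can be supplied anywhere a
#'   model is accepted by providing an object with a `predict` method
#'   returning values in `[0, 1]`.
#' @return Object of class `niche_scorer`.
#' @export
fit_scorer <- function(presences, absences, env, model_kind = "gaussian_logistic") {
  stopifnot(nrow(presences) >= 2, nrow(absences) >= 2)
  factors <- intersect(VULN_FACTORS, names(env))
  df <- bind_rows(
    presences |> select("subcatchment") |> mutate(y = 1L),
    absences |> select("subcatchment") |> mutate(y = 0L)
  ) |>
    inner_join(env, by = "subcatchment")
  keep <- factors[vapply(factors, function(f) sd(df[[f]]) > 1e-10, logical(1))]
  dropped <- setdiff(factors, keep)
  if (length(dropped)) {
    warn(paste0(
      "Dropping zero-variance factor(s): ",
      paste(dropped, collapse = ", ")
    ))
  }
  if (!length(keep)) abort("No usable (non-degenerate) factors to fit on.")
  centers <- vapply(keep, function(f) mean(df[[f]]), numeric(1))
  scales <- vapply(keep, function(f) sd(df[[f]]), numeric(1))
  X <- as_tibble(lapply(setNames(keep, keep), function(f) {
    (df[[f]] - centers[[f]]) / scales[[f]]
  }))
  dat <- bind_cols(tibble(y = df$y), X, as_tibble(lapply(X, function(v) v^2)) |>
    setNames(paste0(keep, "_sq")))
  form <- stats::as.formula(paste(
    "y ~",
    paste(c(keep, paste0(keep, "_sq")), collapse = " + ")
  ))
  fit <- suppressWarnings(glm(form, family = binomial(), data = dat))
  limits <- tibble(
    factor = keep,
    min = unname(vapply(keep, function(f) min(df[[f]]), numeric(1))),
    max = unname(vapply(keep, function(f) max(df[[f]]), numeric(1)))
  )
  structure(
    list(
      coefficients = coef(fit), factors = keep,
      centers = centers, scales = scales,
      training_limits = limits, model_kind = model_kind,
      converged = fit$converged
    ),
    class = "niche_scorer"
  )
}

#' Predict suitability from a fitted scorer
#'
#' @param object A `niche_scorer`.
#' @param newdata A `scenario_stack` (or any tibble with the factor
#'   columns).
#' @param ... Unused.
#' @return Numeric vector of suitabilities in `[0, 1]`, one per row of
#'   `newdata`.
#' @export
predict.niche_scorer <- function(object, newdata, ...) {
  b <- object$coefficients
  eta <- rep(b[["(Intercept)"]], nrow(newdata))
  for (f in object$factors) {
    z <- (newdata[[f]] - object$centers[[f]]) / object$scales[[f]]
    eta <- eta + b[[f]] * z + b[[paste0(f, "_sq")]] * z^2
  }
  plogis(eta)
}

#' @export
print.niche_scorer <- function(x, ...) {
  cat(sprintf(
    "<niche_scorer> kind=%s, factors: %s\n",
    x$model_kind, paste(x$factors, collapse = ", ")
  ))
  invisible(x)
}

#' Estimated niche optima of the built-in scorer
#'
#' @param x A `niche_scorer`.
#' @param ... Unused.
#' @return Tibble: factor, optimum (NA where the fitted quadratic is not
#'   concave), curvature.
#' @method tidy niche_scorer
#' @export
tidy.niche_scorer <- function(x, ...) {
  b <- x$coefficients
  map(x$factors, function(f) {
    b1 <- b[[f]]
    b2 <- b[[paste0(f, "_sq")]]
    opt <- if (is.finite(b2) && b2 < 0) {
      x$centers[[f]] - x$scales[[f]] * b1 / (2 * b2)
    } else {
      NA_real_
    }
    tibble(factor = f, optimum = opt, curvature = b2)
  }) |> bind_rows()
}

#' Evaluate predicted scores against presence/absence labels
#'
#' AUC by the midrank formula; TSS (sensitivity + specificity - 1)
#' maximized over every distinct predicted score as candidate threshold,
#' with a score >= threshold counted as a predicted presence. The smallest
#' score achieving the maximum TSS is returned as the threshold.
#'
#' @param presence_scores,absence_scores Numeric score vectors.
#' @return Object of class `scorer_evaluation`: list(auc, tss,
#'   tss_threshold).
#' @export
evaluate_predictions <- function(presence_scores, absence_scores) {
  stopifnot(length(presence_scores) > 0, length(absence_scores) > 0)
  np <- length(presence_scores)
  na <- length(absence_scores)
  r <- rank(c(presence_scores, absence_scores))
  auc <- (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * na)
  cand <- sort(unique(c(presence_scores, absence_scores)))
  tss <- vapply(cand, function(t) {
    mean(presence_scores >= t) + mean(absence_scores < t) - 1
  }, numeric(1))
  best <- max(tss)
  thr <- cand[which(tss >= best - 1e-12)[1]]
  structure(list(auc = auc, tss = best, tss_threshold = thr),
    class = "scorer_evaluation"
  )
}

#' Evaluate a fitted scorer on held-out localities
#'
#' @param model Object with a `predict` method returning `[0, 1]` scores.
#' @param test_presences,test_absences Locality tibbles with
#'   `subcatchment`.
#' @param env A `scenario_stack`.
#' @return A `scorer_evaluation` (auc, tss, tss_threshold).
#' @export
evaluate_scorer <- function(model, test_presences, test_absences, env) {
  stopifnot(nrow(test_presences) > 0, nrow(test_absences) > 0)
  sc_p <- predict(model, test_presences |> select("subcatchment") |>
    inner_join(env, by = "subcatchment"))
  sc_a <- predict(model, test_absences |> select("subcatchment") |>
    inner_join(env, by = "subcatchment"))
  evaluate_predictions(sc_p, sc_a)
}

#' @method tidy scorer_evaluation
#' @export
tidy.scorer_evaluation <- function(x, ...) {
  tibble(auc = x$auc, tss = x$tss, tss_threshold = x$tss_threshold)
}

#' Fit a TSS-weighted ensemble of replicate scorers
#'
#' Fits `n_replicates` scorers on seeded 70/30 presence/absence splits; each
#' member is weighted by its held-out TSS (negative TSS truncated to 0).
#'
#' @param presences,absences Locality tibbles with `subcatchment`.
#' @param env A `scenario_stack` (training scenario).
#' @param n_replicates Number of replicate fits (default 5).
#' @param train_frac Training fraction of each split (default 0.7).
#' @param seed Integer seed.
#' @return Object of class `suitability_ensemble`: members (model, weight)
#'   and an `evaluations` tibble (replicate, auc, tss, tss_threshold).
#' @export
fit_ensemble <- function(presences, absences, env, n_replicates = 5,
                         train_frac = 0.7, seed = 1) {
  stopifnot(n_replicates >= 1, train_frac > 0, train_frac < 1)
  members <- vector("list", n_replicates)
  evals <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    withr::with_seed(derive_seed(seed, r), {
      ip <- sample.int(nrow(presences)) <= ceiling(train_frac * nrow(presences))
      ia <- sample.int(nrow(absences)) <= ceiling(train_frac * nrow(absences))
    })
    if (sum(!ip) == 0) ip[which(ip)[1]] <- FALSE
    if (sum(!ia) == 0) ia[which(ia)[1]] <- FALSE
    m <- fit_scorer(presences[ip, ], absences[ia, ], env)
    ev <- evaluate_scorer(m, presences[!ip, ], absences[!ia, ], env)
    members[[r]] <- list(model = m, weight = max(ev$tss, 0))
    evals[[r]] <- tidy(ev) |> mutate(replicate = r, .before = 1)
  }
  structure(
    list(members = members, evaluations = bind_rows(evals)),
    class = "suitability_ensemble"
  )
}

#' @export
print.suitability_ensemble <- function(x, ...) {
  cat(sprintf(
    "<suitability_ensemble> %d members, mean TSS %.3f, mean AUC %.3f\n",
    length(x$members), mean(x$evaluations$tss), mean(x$evaluations$auc)
  ))
  invisible(x)
}

#' @method glance suitability_ensemble
#' @export
glance.suitability_ensemble <- function(x, ...) {
  tibble(
    n_members = length(x$members),
    mean_auc = mean(x$evaluations$auc),
    mean_tss = mean(x$evaluations$tss),
    total_weight = sum(map_dbl(x$members, "weight"))
  )
}

#' Pooled training limits of an ensemble
#'
#' Per-factor range over every member's training data, used for clamping.
#'
#' @param ensemble A `suitability_ensemble`.
#' @return Tibble: factor, min, max.
#' @export
ensemble_limits <- function(ensemble) {
  map(ensemble$members, function(m) m$model$training_limits) |>
    bind_rows() |>
    group_by(.data$factor) |>
    summarise(min = min(.data$min), max = max(.data$max), .groups = "drop")
}

#' Project an ensemble onto a scenario
#'
#' Per-subcatchment TSS-weight-normalized mean of member predictions.
#'
#' @param ensemble A `suitability_ensemble`.
#' @param env A `scenario_stack`.
#' @param species Species id stored on the surface (optional).
#' @param tss_threshold Threshold to stamp on the surface (optional; see
#'   [ensemble_threshold()]).
#' @return A `suitability_surface`: tibble (subcatchment, suitability) with
#'   attributes species, scenario, tss_threshold.
#' @export
ensemble_project <- function(ensemble, env, species = NA_character_,
                             tss_threshold = NA_real_) {
  w <- map_dbl(ensemble$members, "weight")
  if (length(w) == 0 || all(w == 0)) {
    abort("Ensemble has no members with positive TSS weight.")
  }
  preds <- map(ensemble$members, function(m) predict(m$model, env))
  s <- Reduce(`+`, map2(preds, w, function(p, wi) p * wi)) / sum(w)
  new_suitability_surface(
    tibble(subcatchment = env$subcatchment, suitability = s),
    species = species, scenario = attr(env, "scenario") %||% NA_character_,
    tss_threshold = tss_threshold
  )
}

#' TSS-maximizing threshold for an ensemble
#'
#' Projects the ensemble on the training scenario and scans candidate
#' thresholds at the supplied presence/absence localities.
#'
#' @inheritParams fit_ensemble
#' @param ensemble A `suitability_ensemble`.
#' @return The threshold (numeric scalar).
#' @export
ensemble_threshold <- function(ensemble, presences, absences, env) {
  surf <- ensemble_project(ensemble, env)
  sc <- setNames(surf$suitability, surf$subcatchment)
  evaluate_predictions(
    sc[presences$subcatchment],
    sc[absences$subcatchment]
  )$tss_threshold
}

new_suitability_surface <- function(tbl, species = NA_character_,
                                    scenario = NA_character_,
                                    tss_threshold = NA_real_) {
  structure(as_tibble(tbl),
    species = species, scenario = scenario, tss_threshold = tss_threshold,
    class = c("suitability_surface", class(tibble()))
  )
}

surface_attrs <- function(surface) {
  list(
    species = attr(surface, "species"),
    scenario = attr(surface, "scenario"),
    tss_threshold = attr(surface, "tss_threshold")
  )
}

#' Clamp projected suitability outside training limits
#'
#' Subcatchments where more than `max_exceed` environmental factors fall
#' outside the training limits have their suitability multiplied by
#' `penalty` (default 0, a hard clamp). With the defaults, one factor out
#' of range is tolerated — only multi-factor extrapolation is penalized.
#'
#' @param surface A `suitability_surface`.
#' @param env The `scenario_stack` the surface was projected on.
#' @param limits Tibble (factor, min, max), e.g. [ensemble_limits()].
#' @param max_exceed Factors allowed outside limits before clamping
#'   (default 1).
#' @param penalty Multiplier applied when clamped, in `[0, 1]` (default 0).
#' @return The clamped `suitability_surface`.
#' @export
clamp_surface <- function(surface, env, limits, max_exceed = 1, penalty = 0) {
  stopifnot(penalty >= 0, penalty <= 1)
  missing <- setdiff(limits$factor, names(env))
  if (length(missing)) {
    abort(paste0("env lacks factor(s): ", paste(missing, collapse = ", ")))
  }
  n_out <- rep(0L, nrow(env))
  for (i in seq_len(nrow(limits))) {
    v <- env[[limits$factor[i]]]
    n_out <- n_out + as.integer(v < limits$min[i] | v > limits$max[i])
  }
  exceed <- tibble(subcatchment = env$subcatchment, n_out = n_out)
  at <- surface_attrs(surface)
  out <- as_tibble(surface) |>
    left_join(exceed, by = "subcatchment") |>
    mutate(suitability = ifelse(.data$n_out > max_exceed,
      .data$suitability * penalty, .data$suitability
    )) |>
    select(-"n_out")
  new_suitability_surface(out, at$species, at$scenario, at$tss_threshold)
}

#' Binarize a suitability surface at its TSS threshold
#'
#' A subcatchment is suitable iff suitability >= threshold (inclusive
#' boundary, so the threshold value itself counts as habitat).
#'
#' @param surface A `suitability_surface` with its `tss_threshold` set.
#' @return Tibble: subcatchment, suitable (logical).
#' @export
binarize_surface <- function(surface) {
  tau <- attr(surface, "tss_threshold")
  if (is.null(tau) || is.na(tau)) {
    abort("Surface has no TSS threshold set; cannot binarize.")
  }
  tibble(
    subcatchment = surface$subcatchment,
    suitable = surface$suitability >= tau
  )
}
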