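#' Build a traversal-cost surface
#'
#' Land cells cost 1; open-water cells cost `water_multiplier` (default 2;
#' 100 for the dispersal-barrier scenario, which makes the sea effectively
#' impassable relative to land routes).
#'
#' @param landscape A `vuln_landscape`.
#' @param water_multiplier Water traversal cost relative to land (>= 1).
#' @return Object of class `cost_surface`: tibble (cell, cost) with
#'   landscape geometry attributes.
#' @export
build_cost_surface <- function(landscape, water_multiplier = 2) {
  stopifnot(water_multiplier >= 1)
  structure(
    tibble(
      cell = landscape$cells$cell,
      cost = ifelse(landscape$cells$is_water, water_multiplier, 1)
    ),
    n_rows = landscape$n_rows, n_cols = landscape$n_cols,
    cell_size = landscape$cell_size, water_multiplier = water_multiplier,
    class = c("cost_surface", class(tibble()))
  )
}

## Edge list of the 8-connected grid graph: each edge weighted
## cell_size * mean(cost of the two endpoint cells) * sqrt(2) if diagonal.
grid_edge_list <- function(n_rows, n_cols, cost, cell_size) {
  id <- matrix(seq_len(n_rows * n_cols), n_rows, n_cols)
  e <- list(
    list(from = id[-n_rows, , drop = FALSE], to = id[-1, , drop = FALSE], d = 1),
    list(from = id[, -n_cols, drop = FALSE], to = id[, -1, drop = FALSE], d = 1),
    list(
      from = id[-n_rows, -n_cols, drop = FALSE],
      to = id[-1, -1, drop = FALSE], d = sqrt(2)
    ),
    list(
      from = id[-1, -n_cols, drop = FALSE],
      to = id[-n_rows, -1, drop = FALSE], d = sqrt(2)
    )
  )
  from <- unlist(lapply(e, function(x) as.vector(x$from)))
  to <- unlist(lapply(e, function(x) as.vector(x$to)))
  dfac <- unlist(lapply(e, function(x) rep(x$d, length(x$from))))
  tibble(
    from = from, to = to,
    weight = cell_size * (cost[from] + cost[to]) / 2 * dfac
  )
}

cost_graph <- function(costs) {
  el <- grid_edge_list(
    attr(costs, "n_rows"), attr(costs, "n_cols"),
    costs$cost, attr(costs, "cell_size")
  )
  g <- igraph::make_empty_graph(n = nrow(costs), directed = FALSE)
  g <- igraph::add_edges(g, rbind(el$from, el$to))
  igraph::E(g)$weight <- el$weight
  g
}

#' Least-cost distances from occurrence cells to all subcatchments
#'
#' Shortest-path (Dijkstra) distance on the 8-connected grid graph with
#' step weight `cell_size * mean(cost of the two endpoint cells)` (times
#' sqrt(2) for diagonal steps), minimized over all source cells. The
#' per-subcatchment distance is read at the member cell nearest the
#' subcatchment centroid; subcatchments containing a source cell are at
#' distance 0. Unreachable subcatchments get `Inf`.
#'
#' @param costs A `cost_surface`.
#' @param sources Integer vector of source cell ids (non-empty), e.g. the
#'   cells of a species' occurrence records.
#' @param landscape The `vuln_landscape` the cost surface was built from.
#' @param species Species id stored on the result (optional).
#' @return Object of class `distance_field`: tibble (subcatchment,
#'   distance_km), with the per-cell distance vector in attribute
#'   `cell_distances`.
#' @export
cost_distance <- function(costs, sources, landscape, species = NA_character_) {
  sources <- unique(as.integer(sources))
  stopifnot(length(sources) >= 1, all(sources >= 1), all(sources <= nrow(costs)))
  g <- cost_graph(costs)
  d <- igraph::distances(g, v = sources, algorithm = "dijkstra")
  dcell <- apply(d, 2L, min)

  cells <- landscape$cells
  subs <- landscape$subcatchments
  # member cell nearest each centroid
  centroid_cell <- vapply(seq_len(nrow(subs)), function(i) {
    mem <- cells[which(cells$subcatchment == subs$subcatchment[i]), ]
    mem$cell[which.min((mem$x - subs$x[i])^2 + (mem$y - subs$y[i])^2)]
  }, integer(1))
  dist_km <- dcell[centroid_cell]
  occupied <- unique(cells$subcatchment[sources])
  dist_km[subs$subcatchment %in% occupied] <- 0
  structure(
    tibble(subcatchment = subs$subcatchment, distance_km = dist_km),
    species = species, cell_distances = dcell,
    class = c("distance_field", class(tibble()))
  )
}

#' Four-parameter logistic dispersal kernel parameters
#'
#' `k(d) = c + (a - c) / (1 + (d / d0)^b)`: dispersal probability 1 near
#' the records, 0.5 at the inflection distance `d0`, falling towards `c`
#' beyond. The default steepness `b = 4` keeps the kernel near 1 well
#' inside `d0` (k = 0.99 at 0.3 d0) and near 0 beyond twice `d0`.
#'
#' @param d0 Inflection (threshold) distance in km.
#' @param b Steepness (> 0; default 4).
#' @param a,c Upper/lower asymptotes (defaults 1 and 0; `a > c`).
#' @return List of class `kernel_params`.
#' @export
kernel_params <- function(d0, b = 4, a = 1, c = 0) {
  stopifnot(d0 > 0, b > 0, a > c)
  structure(list(a = a, c = c, d0 = d0, b = b), class = "kernel_params")
}

#' Dispersal probability at a cost-weighted distance
#'
#' @param d Distance(s) in km (>= 0; `Inf` allowed).
#' @param params A `kernel_params`.
#' @return Dispersal probabilities in `[c, a]`.
#' @export
kernel_value <- function(d, params) {
  stopifnot(all(d >= 0, na.rm = TRUE))
  with(params, c + (a - c) / (1 + (d / d0)^b))
}

#' Weight a suitability surface by dispersal probability
#'
#' Multiplies per-subcatchment suitability by `k(distance)`; infinite
#' distances (unreachable subcatchments) zero the suitability outright,
#' whatever the kernel's lower asymptote. The TSS threshold is carried
#' over unchanged.
#'
#' @param surface A `suitability_surface`.
#' @param distances A `distance_field` on the same subcatchment set.
#' @param params A `kernel_params`.
#' @return The dispersal-weighted `suitability_surface`.
#' @export
apply_kernel <- function(surface, distances, params) {
  at <- surface_attrs(surface)
  d <- distances$distance_km[match(surface$subcatchment, distances$subcatchment)]
  if (anyNA(d)) abort("Distance field does not cover the surface's subcatchments.")
  k <- ifelse(is.infinite(d), 0, kernel_value(d, params))
  new_suitability_surface(
    tibble(subcatchment = surface$subcatchment, suitability = surface$suitability * k),
    at$species, at$scenario, at$tss_threshold
  )
}

#' Rank-sum comparison of two samples (is b stochastically larger than a?)
#'
#' Wilcoxon rank-sum with midranks for ties. The normal approximation uses
#' the tie-corrected variance; `exact = TRUE` enumerates every assignment
#' of the pooled values to groups (feasible for small samples) and returns
#' the exact one-sided permutation p-value.
#'
#' @param a,b Numeric samples (each length >= 2). `Inf` values are ranked
#'   as largest.
#' @param exact Enumerate the exact permutation distribution (requires
#'   `choose(length(a) + length(b), length(b)) <= 1e6`).
#' @return List: z, p_one_sided, statistic (rank sum of `b`), exact.
#' @export
rank_sum_z <- function(a, b, exact = FALSE) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  na <- length(a)
  nb <- length(b)
  n <- na + nb
  pooled <- c(a, b)
  r <- rank(pooled)
  w <- sum(r[(na + 1):n])
  e_w <- nb * (n + 1) / 2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  v_w <- na * nb / 12 * ((n + 1) - tie_term)
  z <- if (v_w <= 0) 0 else (w - e_w) / sqrt(v_w)
  # one-sided p with continuity correction (the discrete rank sum steps by
  # 1/2 at least); the reported z stays uncorrected for the SD-cut scoring
  p <- if (v_w <= 0) 0.5 else pnorm((w - e_w - 0.5) / sqrt(v_w), lower.tail = FALSE)
  if (exact) {
    if (choose(n, nb) > 1e6) abort("Exact enumeration infeasible for this n.")
    combos <- utils::combn(n, nb)
    ws <- colSums(matrix(r[combos], nrow = nb))
    p <- mean(ws >= w - 1e-9)
  }
  list(z = z, p_one_sided = p, statistic = w, exact = exact)
}

#' Habitat-shift score from distances to current vs future habitat
#'
#' Compares the least-cost distances from a species' records to all
#' currently suitable subcatchments against distances to all
#' future-suitable subcatchments with a one-sided rank-sum test (future
#' farther). Score 0 if not significant (z < 1.96, ~ p = 0.05), 1 if
#' significant (1.96 <= z < 3), 2 if beyond three SDs (z >= 3). A species
#' whose future-suitable set is empty scores 2 with a sentinel `z = Inf`
#' and a degenerate flag.
#'
#' @param current_suitable,future_suitable Character vectors of suitable
#'   subcatchment ids.
#' @param distances The species' `distance_field`.
#' @param z_cuts Cuts for scores 1 and 2 (default `c(1.96, 3)`).
#' @return List: score (0/1/2), z, p_one_sided, degenerate.
#' @export
habitat_shift_score <- function(current_suitable, future_suitable, distances,
                                z_cuts = c(1.96, 3)) {
  if (length(future_suitable) == 0) {
    return(list(score = 2L, z = Inf, p_one_sided = 0, degenerate = TRUE))
  }
  if (length(current_suitable) == 0) {
    abort("Current suitable set is empty; habitat shift undefined.")
  }
  d <- setNames(distances$distance_km, distances$subcatchment)
  cur <- unname(d[current_suitable])
  fut <- unname(d[future_suitable])
  if (length(cur) < 2 || length(fut) < 2) {
    # too small for a rank test: fall back on a direct comparison
    z <- if (mean(fut) > mean(cur)) Inf else 0
    score <- if (is.infinite(z)) 2L else 0L
    return(list(score = score, z = z, p_one_sided = ifelse(score == 2L, 0, 0.5), degenerate = FALSE))
  }
  rs <- rank_sum_z(cur, fut)
  score <- if (rs$z >= z_cuts[2]) 2L else if (rs$z >= z_cuts[1]) 1L else 0L
  list(score = score, z = rs$z, p_one_sided = rs$p_one_sided, degenerate = FALSE)
}

#' Threshold-sweep score: dependence of sensitivity on dispersal reach
#'
#' Sweeps the kernel inflection distance over `n_levels` equally spaced
#' values between the current habitat limit and the future threshold,
#' recomputing the dispersal-weighted future surface and the sensitivity
#' weight S at each level. Within each tercile of levels (low / medium /
#' high d0, `n_levels / 3` points each) S is regressed on `ln(d0)` by
#' ordinary least squares. The species scores 3 if the high-tercile slope
#' is at or below `slope_cut`, else 2 for the medium tercile, else 1 for
#' the low tercile, else 0 — steep loss at generous thresholds marks
#' species whose future habitat is concentrated far away. S is
#' non-increasing in d0, so meaningful slopes are negative; the cut's
#' magnitude of 1 mirrors the sensitivity cut. A tercile containing levels
#' where the future total is zero (S undefined, habitat gone) is treated
#' as maximally steep (slope `-Inf`); if every level is degenerate the
#' species scores 3 with a flag.
#'
#' @param future_unkerneled Future `suitability_surface` before dispersal
#'   weighting (clamped).
#' @param current_surface Current `suitability_surface` (dispersal-
#'   constrained), the fixed baseline for S.
#' @param distances The species' `distance_field`.
#' @param base_threshold Current habitat limit in km (default 300).
#' @param future_threshold Future kernel threshold in km (630 for 2055,
#'   1080 for 2085).
#' @param n_levels Number of sweep levels, divisible by 3 (default 30).
#' @param slope_cut Slope cut on S vs ln(d0) (default -1).
#' @param b Kernel steepness (default 4).
#' @return List: sweep_score (0-3), slopes (low/medium/high), s_values
#'   tibble (d0, S), degenerate.
#' @export
threshold_sweep <- function(future_unkerneled, current_surface, distances,
                            base_threshold = 300, future_threshold,
                            n_levels = 30, slope_cut = -1, b = 4) {
  stopifnot(base_threshold < future_threshold, n_levels %% 3 == 0)
  d0s <- seq(base_threshold, future_threshold, length.out = n_levels)
  S <- vapply(d0s, function(d0) {
    surf <- apply_kernel(future_unkerneled, distances, kernel_params(d0, b = b))
    res <- tryCatch(sensitivity_weight(current_surface, surf),
      error = function(e) NULL
    )
    if (is.null(res) || res$degenerate) NA_real_ else res$S
  }, numeric(1))
  if (all(is.na(S))) {
    return(list(
      sweep_score = 3L,
      slopes = c(low = -Inf, medium = -Inf, high = -Inf),
      s_values = tibble(d0 = d0s, S = S), degenerate = TRUE
    ))
  }
  c(sweep_slopes(d0s, S, slope_cut = slope_cut),
    list(s_values = tibble(d0 = d0s, S = S), degenerate = FALSE)
  )
}

#' Tercile slopes and sweep score for a sensitivity-vs-threshold series
#'
#' The regression and scoring core of [threshold_sweep()], exposed so a
#' sweep computed elsewhere (or a constructed series) can be scored. Fits
#' ordinary least squares of S on `ln(d0)` within each consecutive tercile
#' of levels; `NA` values of S (future habitat entirely gone at that
#' level) make their tercile maximally steep (`-Inf`).
#'
#' @param d0 Threshold distances (km), increasing, length divisible by 3.
#' @param S Sensitivity weight at each threshold.
#' @param slope_cut Slope cut (default -1).
#' @return List: sweep_score (0-3), slopes (named low/medium/high).
#' @export
sweep_slopes <- function(d0, S, slope_cut = -1) {
  n <- length(d0)
  stopifnot(n %% 3 == 0, length(S) == n)
  third <- n / 3
  terciles <- list(
    low = seq_len(third),
    medium = third + seq_len(third),
    high = 2 * third + seq_len(third)
  )
  slopes <- vapply(terciles, function(idx) {
    s <- S[idx]
    if (anyNA(s)) {
      return(-Inf)
    }
    x <- log(d0[idx])
    if (sd(s) == 0) {
      return(0)
    }
    unname(coef(lm(s ~ x))[2])
  }, numeric(1))
  score <- if (slopes[["high"]] <= slope_cut) {
    3L
  } else if (slopes[["medium"]] <= slope_cut) {
    2L
  } else if (slopes[["low"]] <= slope_cut) 1L else 0L
  list(sweep_score = score, slopes = slopes)
}

#' Combine the two dispersal scores into dispersal pressure
#'
#' Total = habitat-shift score (0-2) + threshold-sweep score (0-3), so at
#' most 5 points; species scoring 3 or more are under dispersal pressure.
#'
#' @param shift_score Habitat-shift score in 0..2.
#' @param sweep_score Threshold-sweep score in 0..3.
#' @param shift_z Optional z statistic to carry along.
#' @param slopes Optional named tercile slopes to carry along.
#' @param pressure_cut Flagging cut on the total (default 3).
#' @return Object of class `dispersal_result`: list(shift_score,
#'   sweep_score, total, pressured, shift_z, slopes).
#' @export
dispersal_pressure <- function(shift_score, sweep_score, shift_z = NA_real_,
                               slopes = NULL, pressure_cut = 3) {
  stopifnot(shift_score %in% 0:2, sweep_score %in% 0:3)
  total <- as.integer(shift_score + sweep_score)
  structure(
    list(
      shift_score = as.integer(shift_score),
      sweep_score = as.integer(sweep_score),
      total = total, pressured = total >= pressure_cut,
      shift_z = shift_z,
      slopes = slopes %||% c(low = NA_real_, medium = NA_real_, high = NA_real_)
    ),
    class = "dispersal_result"
  )
}

#' @method tidy dispersal_result
#' @export
tidy.dispersal_result <- function(x, ...) {
  tibble(
    shift_score = x$shift_score, shift_z = x$shift_z,
    slope_low = unname(x$slopes[["low"]]),
    slope_medium = unname(x$slopes[["medium"]]),
    slope_high = unname(x$slopes[["high"]]),
    sweep_score = x$sweep_score, total = x$total, pressured = x$pressured
  )
}
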