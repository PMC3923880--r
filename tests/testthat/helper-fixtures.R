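# Shared fixtures and independent oracles for the test suite.

tiny_landscape <- function(n_rows = 12, n_cols = 12, n_sub = 10,
                           sea_fraction = 0.15, seed = 42, cell_size = 25) {
  generate_landscape(n_rows, n_cols,
    n_subcatchments = n_sub,
    cell_size = cell_size, sea_fraction = sea_fraction, seed = seed
  )
}

# wide scenario stack from explicit per-subcatchment values
make_stack <- function(df, scenario = "current") {
  streamvuln:::new_scenario_stack(tibble::as_tibble(df), scenario)
}

# a full 7-factor stack where every factor takes the supplied values
make_stack7 <- function(subcatchments, values, scenario = "current") {
  df <- tibble::tibble(subcatchment = subcatchments)
  for (f in streamvuln:::VULN_FACTORS) df[[f]] <- values
  make_stack(df, scenario)
}

make_surface <- function(subcatchments, suitability, tau = 0.5,
                         species = "spX", scenario = "current") {
  streamvuln:::new_suitability_surface(
    tibble::tibble(subcatchment = subcatchments, suitability = suitability),
    species = species, scenario = scenario, tss_threshold = tau
  )
}

make_distances <- function(subcatchments, km, species = "spX") {
  structure(
    tibble::tibble(subcatchment = subcatchments, distance_km = km),
    species = species,
    class = c("distance_field", class(tibble::tibble()))
  )
}

# ---- independent oracles -------------------------------------------------

# AUC by explicit concordant-pair counting (ties count 1/2)
auc_pairs <- function(pres, abs) {
  conc <- outer(pres, abs, function(p, a) (p > a) + 0.5 * (p == a))
  mean(conc)
}

# exact one-sided permutation p (b stochastically larger) by full enumeration
perm_p_exact <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  nb <- length(b)
  w_obs <- sum(r[(length(a) + 1):length(pooled)])
  combos <- utils::combn(length(pooled), nb)
  ws <- colSums(matrix(r[combos], nrow = nb))
  mean(ws >= w_obs - 1e-9)
}

# closed-form OLS slope
ols_slope <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

# exhaustive least-cost path search on a small grid: depth-first over simple
# paths with cost-bound pruning (prunes only provably worse paths, so the
# result equals full enumeration)
brute_force_cost <- function(n_rows, n_cols, cost, cell_size, from, to) {
  nbr <- streamvuln:::neighbour_matrix(n_rows, n_cols)
  best <- Inf
  visited <- rep(FALSE, n_rows * n_cols)
  step_w <- function(i, j, k) {
    diag <- k > 4
    cell_size * (cost[i] + cost[j]) / 2 * if (diag) sqrt(2) else 1
  }
  dfs <- function(i, acc) {
    if (acc >= best) {
      return()
    }
    if (i == to) {
      best <<- acc
      return()
    }
    visited[i] <<- TRUE
    for (k in seq_len(8L)) {
      j <- nbr[i, k]
      if (!is.na(j) && !visited[j]) dfs(j, acc + step_w(i, j, k))
    }
    visited[i] <<- FALSE
  }
  dfs(from, 0)
  best
}

# small complete assessment inputs built around an explicit geometry
demo_pipeline_config <- function(seed = 11) {
  vuln_config(
    seed = seed,
    grid = list(n_rows = 28, n_cols = 28, n_subcatchments = 90),
    species = list(n_species = 8, n_records_range = c(100, 250)),
    pseudo_absences = list(n_total = 120),
    ensemble = list(n_replicates = 3)
  )
}
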