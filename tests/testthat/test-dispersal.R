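test_that("cost surfaces put unit cost on land and the multiplier on water", {
  dry <- generate_landscape(8, 8, n_subcatchments = 6, sea_fraction = 0, seed = 2)
  expect_true(all(build_cost_surface(dry, 2)$cost == 1))

  wet <- generate_landscape(10, 10, n_subcatchments = 6, sea_fraction = 0.3, seed = 3)
  for (mult in c(2, 100)) {
    cs <- build_cost_surface(wet, mult)
    expect_true(all(cs$cost[wet$cells$is_water] == mult))
    expect_true(all(cs$cost[!wet$cells$is_water] == 1))
  }
  expect_error(build_cost_surface(wet, 0.5))
})

# all-land landscape with one subcatchment per cell: distances read exactly
# at each cell
lattice_landscape <- function(n, cell_size = 1) {
  ls <- generate_landscape(n, n,
    n_subcatchments = n * n, sea_fraction = 0,
    cell_size = cell_size, seed = 1
  )
  ls
}

test_that("uniform-cost distances equal the 8-connected geometric metric", {
  ls <- lattice_landscape(6)
  cs <- build_cost_surface(ls, 2)
  src <- ls$cells$cell[ls$cells$row == 1 & ls$cells$col == 1]
  df <- cost_distance(cs, src, ls)
  d <- attr(df, "cell_distances")
  expect_equal(d[src], 0)
  straight <- ls$cells$cell[ls$cells$row == 1 & ls$cells$col == 6]
  expect_equal(d[straight], 5) # 5 unit steps
  diag <- ls$cells$cell[ls$cells$row == 4 & ls$cells$col == 4]
  expect_equal(d[diag], 3 * sqrt(2), tolerance = 1e-12)
  # Chebyshev-style metric everywhere on uniform cost
  geom <- pmax(ls$cells$row - 1, ls$cells$col - 1) +
    (sqrt(2) - 1) * pmin(ls$cells$row - 1, ls$cells$col - 1)
  expect_equal(unname(d), geom, tolerance = 1e-9)
})

test_that("least-cost distances equal exhaustive path enumeration on small grids", {
  # several <= 5x5 fixtures including a costly water strip down the middle
  fixtures <- list(
    list(n = 3, water_cols = integer(0), mult = 2),
    list(n = 4, water_cols = 2, mult = 2),
    list(n = 5, water_cols = 3, mult = 2),
    list(n = 5, water_cols = 3, mult = 100),
    list(n = 5, water_cols = c(2, 4), mult = 3)
  )
  for (fx in fixtures) {
    n <- fx$n
    ls <- lattice_landscape(n)
    is_water <- ls$cells$col %in% fx$water_cols
    cost <- ifelse(is_water, fx$mult, 1)
    cs <- build_cost_surface(ls, fx$mult)
    cs$cost <- cost # impose the synthetic water strip
    from <- ls$cells$cell[ls$cells$row == 2 & ls$cells$col == 1]
    df <- cost_distance(cs, from, ls)
    d <- attr(df, "cell_distances")
    for (target in sample(seq_len(n * n), 6)) {
      oracle <- brute_force_cost(n, n, cost, 1, from, target)
      expect_equal(unname(d[target]), oracle, tolerance = 1e-9)
    }
  }
})

test_that("distance fields respect triangle consistency over edges", {
  ls <- tiny_landscape(n_rows = 10, n_cols = 10, n_sub = 12, seed = 5)
  cs <- build_cost_surface(ls, 2)
  src <- ls$cells$cell[!ls$cells$is_water][1:3]
  d <- attr(cost_distance(cs, src, ls), "cell_distances")
  el <- streamvuln:::grid_edge_list(10, 10, cs$cost, ls$cell_size)
  expect_true(all(d[el$to] <= d[el$from] + el$weight + 1e-9))
  expect_true(all(d[el$from] <= d[el$to] + el$weight + 1e-9))
})

test_that("the 4PL kernel has unit start, half-way inflection and monotone decay", {
  kp <- kernel_params(d0 = 300)
  expect_equal(kernel_value(0, kp), 1, tolerance = 1e-12)
  expect_equal(kernel_value(300, kp), 0.5, tolerance = 1e-12)

  withr::with_seed(11, {
    for (i in 1:1000) {
      p <- kernel_params(
        d0 = runif(1, 10, 2000), b = runif(1, 0.5, 8),
        a = 1, c = runif(1, 0, 0.5)
      )
      d1 <- runif(1, 0, 3000)
      d2 <- d1 + runif(1, 0, 3000)
      k1 <- kernel_value(d1, p)
      k2 <- kernel_value(d2, p)
      expect_gte(k1 + 1e-12, k2)
      expect_true(k1 <= p$a + 1e-12 && k2 >= p$c - 1e-12)
      expect_equal(kernel_value(p$d0, p), (p$a + p$c) / 2, tolerance = 1e-9)
    }
  })

  # widening thresholds order the curves pointwise: 300 <= 630 <= 1080
  d <- seq(0, 3000, by = 10)
  k300 <- kernel_value(d, kernel_params(300))
  k630 <- kernel_value(d, kernel_params(630))
  k1080 <- kernel_value(d, kernel_params(1080))
  expect_true(all(k300 <= k630 + 1e-12))
  expect_true(all(k630 <= k1080 + 1e-12))
})

test_that("kernel weighting scales suitability and zeroes unreachable habitat", {
  subs <- sprintf("S%02d", 1:5)
  surf <- make_surface(subs, c(0.8, 0.8, 0.8, 0.5, 0.9), tau = 0.3)
  kp <- kernel_params(d0 = 300, b = 4)

  near <- apply_kernel(surf, make_distances(subs, rep(0, 5)), kp)
  expect_equal(near$suitability, surf$suitability, tolerance = 1e-12)

  at_d0 <- apply_kernel(surf, make_distances(subs, rep(300, 5)), kp)
  expect_equal(at_d0$suitability[1], 0.4, tolerance = 1e-12)

  far <- apply_kernel(surf, make_distances(subs, rep(3000, 5)), kp)
  expect_true(all(far$suitability < 0.001 * surf$suitability))

  inf <- apply_kernel(surf, make_distances(subs, c(0, Inf, Inf, 0, 0)), kp)
  expect_equal(inf$suitability[2:3], c(0, 0))
  expect_true(all(inf$suitability <= surf$suitability + 1e-12))
  expect_equal(attr(inf, "tss_threshold"), 0.3)
})

test_that("rank_sum_z matches exact enumeration and wilcox.test", {
  ex <- rank_sum_z(c(1, 2), c(3, 4), exact = TRUE)
  expect_equal(ex$p_one_sided, 1 / 6, tolerance = 1e-12)

  same <- rank_sum_z(rep(1:4, 2), rep(1:4, 2))
  expect_equal(same$z, 0, tolerance = 1e-9)
  # continuity correction nudges the one-sided p just past one half
  expect_equal(same$p_one_sided, 0.5, tolerance = 0.05)

  deg <- rank_sum_z(rep(2, 5), rep(2, 5))
  expect_equal(deg$z, 0)
  expect_equal(deg$p_one_sided, 0.5)

  # normal approximation tracks the exact permutation p for small n
  withr::with_seed(12, {
    for (i in 1:50) {
      na <- sample(3:8, 1)
      nb <- sample(3:8, 1)
      a <- round(rnorm(na, 0, 2), 1)
      b <- round(rnorm(nb, sample(0:2, 1), 2), 1)
      rs <- rank_sum_z(a, b)
      expect_lt(abs(rs$p_one_sided - perm_p_exact(a, b)), 0.05)
      # cross-check against the standard implementation (no continuity corr.)
      wt <- suppressWarnings(stats::wilcox.test(b, a,
        alternative = "greater",
        exact = FALSE, correct = TRUE
      ))
      expect_equal(rs$p_one_sided, wt$p.value, tolerance = 1e-9)
    }
  })
})

test_that("habitat-shift scoring bins the z statistic", {
  subs <- sprintf("S%03d", 1:60)
  d <- make_distances(subs, seq(10, 600, by = 10))

  no_shift <- habitat_shift_score(subs[1:30], subs[1:30], d)
  expect_equal(no_shift$score, 0L)

  # future habitat 500 km beyond the current band, 30 vs 30
  far <- habitat_shift_score(subs[1:30], subs[31:60] , make_distances(
    subs, c(seq(10, 300, by = 10), seq(10, 300, by = 10) + 500)
  ))
  expect_equal(far$score, 2L)
  expect_gte(far$z, 3)
  # the z agrees with the rank-sum computed on the same samples
  oracle <- rank_sum_z(seq(10, 300, by = 10), seq(10, 300, by = 10) + 500)
  expect_equal(far$z, oracle$z)

  # partial overlap engineered to land in the significant-but-not-extreme band
  cur <- seq(0, 145, by = 5)
  fut <- cur + 30
  mid <- habitat_shift_score(
    sprintf("C%02d", seq_along(cur)), sprintf("F%02d", seq_along(fut)),
    make_distances(c(sprintf("C%02d", seq_along(cur)), sprintf("F%02d", seq_along(fut))),
      c(cur, fut)
    )
  )
  z_direct <- rank_sum_z(cur, fut)$z
  expect_gte(z_direct, 1.96)
  expect_lt(z_direct, 3)
  expect_equal(mid$score, 1L)

  gone <- habitat_shift_score(subs[1:30], character(0), d)
  expect_equal(gone$score, 2L)
  expect_true(is.infinite(gone$z))
  expect_true(gone$degenerate)
})

test_that("sweep slopes reproduce closed-form least squares and the scoring ladder", {
  d0 <- seq(300, 1080, length.out = 30)

  flat <- sweep_slopes(d0, rep(2.2, 30))
  expect_equal(unname(flat$slopes), c(0, 0, 0))
  expect_equal(flat$sweep_score, 0L)

  # S = -2 ln(d0) + c: every tercile slope is exactly -2
  S <- -2 * log(d0) + 17
  sw <- sweep_slopes(d0, S)
  expect_equal(unname(sw$slopes), rep(-2, 3), tolerance = 1e-9)
  expect_equal(sw$sweep_score, 3L)
  for (idx in list(1:10, 11:20, 21:30)) {
    expect_equal(ols_slope(log(d0[idx]), S[idx]), -2, tolerance = 1e-9)
  }

  # steep only at low thresholds -> score 1
  S1 <- c(-3 * log(d0[1:10]), rep(-3 * log(d0[10]), 20))
  sw1 <- sweep_slopes(d0, S1)
  expect_equal(sw1$sweep_score, 1L)
  expect_equal(unname(sw1$slopes[1]), -3, tolerance = 1e-9)
  expect_equal(unname(sw1$slopes[2:3]), c(0, 0))

  # steep at medium only -> 2; NA (vanished habitat) in the high tercile -> 3
  S2 <- c(rep(0, 10), -4 * log(d0[11:20]), rep(-4 * log(d0[20]), 10))
  expect_equal(sweep_slopes(d0, S2)$sweep_score, 2L)
  S3 <- c(rep(0, 20), rep(NA_real_, 10))
  sw3 <- sweep_slopes(d0, S3)
  expect_equal(sw3$sweep_score, 3L)
  expect_equal(unname(sw3$slopes[3]), -Inf)
})

test_that("threshold_sweep recomputes S across kernel levels on real surfaces", {
  subs <- sprintf("S%03d", 1:40)
  # current habitat near the records, future habitat pushed far away
  cur <- make_surface(subs, c(rep(0.9, 20), rep(0.05, 20)), tau = 0.2, scenario = "current")
  fut <- make_surface(subs, c(rep(0.05, 20), rep(0.9, 20)), tau = 0.2, scenario = "future")
  d <- make_distances(subs, c(rep(0, 20), rep(700, 20)))
  sw <- threshold_sweep(fut, cur, d, base_threshold = 300, future_threshold = 1080)
  # S(d0) must be non-increasing: larger reach keeps more future habitat
  s <- sw$s_values$S
  expect_true(all(diff(s[!is.na(s)]) <= 1e-9))
  expect_true(all(unlist(sw$slopes) <= 1e-9))
  expect_gte(sw$sweep_score, 1L) # far-shifted habitat must register pressure

  # habitat entirely unreachable at any level: degenerate, max score
  d_inf <- make_distances(subs, c(rep(0, 20), rep(Inf, 20)))
  sw_inf <- threshold_sweep(fut, cur, d_inf, base_threshold = 300, future_threshold = 1080)
  expect_true(sw_inf$degenerate)
  expect_equal(sw_inf$sweep_score, 3L)
})

test_that("dispersal pressure totals the two scores and flags at three", {
  top <- dispersal_pressure(2, 3)
  expect_equal(top$total, 5L)
  expect_true(top$pressured)

  none <- dispersal_pressure(0, 0)
  expect_equal(none$total, 0L)
  expect_false(none$pressured)

  expect_true(dispersal_pressure(1, 2)$pressured) # boundary
  expect_false(dispersal_pressure(1, 1)$pressured)

  combos <- expand.grid(shift = 0:2, sweep = 0:3)
  totals <- mapply(function(s, w) dispersal_pressure(s, w)$total, combos$shift, combos$sweep)
  expect_equal(max(totals), 5L)
  expect_equal(min(totals), 0L)
  flags <- mapply(function(s, w) dispersal_pressure(s, w)$pressured, combos$shift, combos$sweep)
  expect_equal(flags, totals >= 3)
})
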