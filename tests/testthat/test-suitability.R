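ls <- tiny_landscape(seed = 31)
st <- generate_scenarios(ls, seed = 32)

test_that("subcatchment aggregation is a plain group mean", {
  n <- nrow(ls$cells)
  uniform <- rep(3.25, n)
  agg <- aggregate_to_subcatchments(uniform, ls)
  expect_true(all(agg$value == 3.25))

  withr::with_seed(1, vals <- rnorm(n))
  agg2 <- aggregate_to_subcatchments(vals, ls)
  oracle <- tapply(vals[!is.na(ls$cells$subcatchment)],
    ls$cells$subcatchment[!is.na(ls$cells$subcatchment)], mean)
  expect_equal(agg2$value, as.numeric(oracle[agg2$subcatchment]), tolerance = 1e-12)

  # a subcatchment whose cells carry no values is an explicit error
  sc1 <- ls$subcatchments$subcatchment[1]
  vals[which(ls$cells$subcatchment == sc1)] <- NA
  expect_error(aggregate_to_subcatchments(vals, ls), sc1)
})

test_that("pseudo-absence eligibility follows the radius and exclusion rules", {
  # hand-built geometry: presences at x = 0, candidates at 250 and 350 km
  pres <- tibble::tibble(species = "a", x = 0, y = 0, subcatchment = "P1")
  bg <- tibble::tibble(
    species = c("b", "b", "b"),
    x = c(250, 350, 10), y = 0,
    subcatchment = c("B1", "B2", "P1")
  )
  out <- select_pseudo_absences(pres, bg, ls, n_total = 1, radius_km = 300, seed = 1)
  expect_equal(out$subcatchment, "B1") # 250 km in, 350 km out, P1 excluded

  # supplementation: eligible pool smaller than n_total
  out2 <- select_pseudo_absences(pres, bg, ls, n_total = 30, radius_km = 300, seed = 1)
  expect_equal(nrow(out2), 30)
  expect_equal(sum(out2$source == "background"), 1)
  expect_equal(sum(out2$source == "random"), 29)
  expect_false(any(out2$subcatchment %in% pres$subcatchment))

  # exhausting the candidate pool is an explicit error
  expect_error(
    select_pseudo_absences(pres, bg, ls, n_total = 10000, radius_km = 300, seed = 1),
    "candidates"
  )
})

test_that("the scorer separates a one-factor signal and records training limits", {
  withr::with_seed(5, {
    pres_v <- 10 + rnorm(30, sd = 0.1)
    abs_v <- 0 + rnorm(30, sd = 0.1)
  })
  env <- make_stack7(sprintf("S%03d", 1:60), c(pres_v, abs_v))
  env <- env[, c("subcatchment", "tmean")] # single factor
  env <- make_stack(env)
  pres <- tibble::tibble(subcatchment = sprintf("S%03d", 1:30))
  abs <- tibble::tibble(subcatchment = sprintf("S%03d", 31:60))
  m <- fit_scorer(pres, abs, env)
  expect_equal(m$training_limits$min, min(c(pres_v, abs_v)))
  expect_equal(m$training_limits$max, max(c(pres_v, abs_v)))

  ev <- evaluate_scorer(m, pres, abs, env)
  sc_p <- predict(m, env[1:30, ])
  sc_a <- predict(m, env[31:60, ])
  expect_equal(ev$auc, auc_pairs(sc_p, sc_a)) # brute-force pair oracle
  expect_equal(ev$auc, 1.0)
})

test_that("a no-signal fit gives chance-level held-out AUC", {
  aucs <- vapply(1:20, function(seed) {
    withr::with_seed(seed, {
      v <- rnorm(120)
      lab <- rep(c(1, 0), each = 60)
    })
    env <- make_stack(tibble::tibble(subcatchment = sprintf("S%03d", 1:120), tmean = v))
    pres <- tibble::tibble(subcatchment = sprintf("S%03d", which(lab == 1)))
    abs <- tibble::tibble(subcatchment = sprintf("S%03d", which(lab == 0)))
    tr_p <- pres[1:40, ]; te_p <- pres[41:60, ]
    tr_a <- abs[1:40, ]; te_a <- abs[41:60, ]
    evaluate_scorer(fit_scorer(tr_p, tr_a, env), te_p, te_a, env)$auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("zero-variance factors are dropped with a warning", {
  env <- make_stack(tibble::tibble(
    subcatchment = sprintf("S%02d", 1:20),
    tmean = c(rnorm(10, 5), rnorm(10, 0)),
    flow = 7 # constant
  ))
  pres <- tibble::tibble(subcatchment = sprintf("S%02d", 1:10))
  abs <- tibble::tibble(subcatchment = sprintf("S%02d", 11:20))
  expect_warning(m <- fit_scorer(pres, abs, env), "flow")
  expect_false("flow" %in% m$factors)
})

test_that("TSS maximization scans every distinct score", {
  ev <- evaluate_predictions(c(0.9, 0.8), c(0.7, 0.1))
  expect_equal(ev$auc, 1.0)
  expect_equal(ev$tss, 1.0)
  expect_equal(ev$tss_threshold, 0.8)

  # identical score sets carry no skill
  ev2 <- evaluate_predictions(c(0.2, 0.5, 0.9), c(0.2, 0.5, 0.9))
  expect_equal(ev2$tss, 0)

  # perfect separation of n vs n
  ev3 <- evaluate_predictions(seq(0.6, 0.9, length.out = 10), seq(0.1, 0.4, length.out = 10))
  expect_equal(ev3$auc, 1.0)
  expect_equal(ev3$tss, 1.0)

  # optimality against a brute-force scan, and AUC against pROC, on random fixtures
  for (seed in 1:10) {
    withr::with_seed(seed, {
      p <- round(runif(12), 2)
      a <- round(runif(15), 2)
    })
    ev <- evaluate_predictions(p, a)
    cand <- sort(unique(c(p, a)))
    tss_all <- vapply(cand, function(t) mean(p >= t) + mean(a < t) - 1, numeric(1))
    expect_equal(ev$tss, max(tss_all), tolerance = 1e-12)
    expect_equal(ev$auc, auc_pairs(p, a), tolerance = 1e-12)
    proc <- suppressMessages(pROC::auc(
      rep(c(1, 0), c(length(p), length(a))), c(p, a), direction = "<"
    ))
    expect_equal(ev$auc, as.numeric(proc), tolerance = 1e-12)
  }
})

test_that("ensemble projection is the TSS-weighted mean, bounded by members", {
  subs <- st$current$subcatchment
  m1 <- list(model = structure(list(v = 0.2), class = "const_scorer"), weight = 0.5)
  m2 <- list(model = structure(list(v = 0.6), class = "const_scorer"), weight = 0.5)
  registerS3method("predict", "const_scorer",
    function(object, newdata, ...) rep(object$v, nrow(newdata)),
    envir = asNamespace("stats")
  )

  ens <- structure(list(members = list(m1, m2)), class = "suitability_ensemble")
  surf <- ensemble_project(ens, st$current)
  expect_true(all(abs(surf$suitability - 0.4) < 1e-12))

  ens2 <- structure(
    list(members = list(
      list(model = m1$model, weight = 0.2),
      list(model = structure(list(v = 1.0), class = "const_scorer"), weight = 0.8)
    )),
    class = "suitability_ensemble"
  )
  surf2 <- ensemble_project(ens2, st$current)
  expect_true(all(abs(surf2$suitability - (0.2 * 0.2 + 1.0 * 0.8)) < 1e-12))

  # single member passes through; all-zero weights error
  ens3 <- structure(list(members = list(m1)), class = "suitability_ensemble")
  expect_true(all(abs(ensemble_project(ens3, st$current)$suitability - 0.2) < 1e-12))
  ens4 <- structure(
    list(members = list(list(model = m1$model, weight = 0))),
    class = "suitability_ensemble"
  )
  expect_error(ensemble_project(ens4, st$current), "weight")

  # on real fits, the projection lies within the member envelope
  ls2 <- tiny_landscape(n_rows = 18, n_cols = 18, n_sub = 40, seed = 38)
  st2 <- generate_scenarios(ls2, seed = 39)
  ni <- generate_species_truth(1, st2$current, seed = 33)
  occ <- sample_occurrences(ni, ls2, st2$current, 250, seed = 34)
  pres <- occ
  bg <- ls2$cells |>
    dplyr::filter(!is_water) |>
    dplyr::transmute(species = "bg", x, y, subcatchment)
  pa <- select_pseudo_absences(occ, bg, ls2, n_total = 120, seed = 35)
  ens5 <- fit_ensemble(pres, pa, st2$current, n_replicates = 3, seed = 36)
  surf5 <- ensemble_project(ens5, st2$current)
  member_preds <- sapply(ens5$members, function(m) predict(m$model, st2$current))
  expect_true(all(surf5$suitability >= apply(member_preds, 1, min) - 1e-12))
  expect_true(all(surf5$suitability <= apply(member_preds, 1, max) + 1e-12))
})

test_that("clamping penalizes only multi-factor extrapolation and never raises suitability", {
  subs <- sprintf("S%02d", 1:4)
  env <- make_stack(tibble::tibble(
    subcatchment = subs,
    tmean = c(10, 25, 25, 10), # limits [5, 20]: rows 2 and 3 outside
    flow = c(100, 100, 900, 100) # limits [50, 500]: row 3 outside
  ))
  limits <- tibble::tibble(factor = c("tmean", "flow"), min = c(5, 50), max = c(20, 500))
  surf <- make_surface(subs, c(0.8, 0.8, 0.8, 0.8), tau = 0.5)
  out <- clamp_surface(surf, env, limits)
  expect_equal(out$suitability, c(0.8, 0.8, 0, 0.8)) # only the 2-factor breach clamps
  expect_true(all(out$suitability <= surf$suitability))

  all_in <- make_stack(tibble::tibble(
    subcatchment = subs, tmean = rep(10, 4), flow = rep(100, 4)
  ))
  expect_equal(clamp_surface(surf, all_in, limits)$suitability, surf$suitability)

  half <- clamp_surface(surf, env, limits, penalty = 0.5)
  expect_equal(half$suitability, c(0.8, 0.8, 0.4, 0.8))
})

test_that("binarization uses an inclusive threshold", {
  tau <- 0.37
  subs <- sprintf("S%02d", 1:5)
  suit <- c(tau - 1e-9, tau, tau + 1e-9, 0, 1)
  mask <- binarize_surface(make_surface(subs, suit, tau = tau))
  expect_equal(mask$suitable, suit >= tau) # elementwise oracle
  expect_equal(mask$suitable, c(FALSE, TRUE, TRUE, FALSE, TRUE))

  none <- binarize_surface(make_surface(subs, rep(0.1, 5), tau = 0.9))
  expect_false(any(none$suitable))
  expect_error(binarize_surface(make_surface(subs, suit, tau = NA_real_)), "threshold")
})

test_that("the built-in scorer recovers strong synthetic niches", {
  # strong signal: peak 0.95, tolerances at half the factor SD
  res <- lapply(1:20, function(seed) {
    lsr <- generate_landscape(26, 26,
      n_subcatchments = 180, sea_fraction = 0.1,
      seed = 1000 + seed
    )
    str <- generate_scenarios(lsr, seed = 2000 + seed)
    ni <- generate_species_truth(1, str$current,
      niche_spread = list(
        tolerance_range = c(0.5, 0.5), peak_range = c(0.95, 0.95)
      ),
      seed = 3000 + seed
    )
    occ <- sample_occurrences(ni, lsr, str$current, 500, seed = 4000 + seed)
    bg <- lsr$cells |>
      dplyr::filter(!is_water) |>
      dplyr::transmute(species = "bg", x, y, subcatchment)
    pa <- select_pseudo_absences(occ, bg, lsr, n_total = 400, seed = 5000 + seed)
    withr::with_seed(6000 + seed, {
      ip <- sample.int(nrow(occ)) <= 0.7 * nrow(occ)
      ia <- sample.int(nrow(pa)) <= 0.7 * nrow(pa)
    })
    m <- fit_scorer(occ[ip, ], pa[ia, ], str$current)
    ev <- evaluate_scorer(m, occ[!ip, ], pa[!ia, ], str$current)
    est <- tidy(m)
    err <- abs(est$optimum - ni$optimum[match(est$factor, ni$factor)]) /
      ni$tolerance[match(est$factor, ni$factor)]
    list(auc = ev$auc, err = err)
  })
  aucs <- vapply(res, function(r) r$auc, numeric(1))
  expect_gte(median(aucs), 0.9)
  err_all <- unlist(lapply(res, function(r) r$err))
  expect_lte(median(err_all, na.rm = TRUE), 0.5)
})
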