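# msd_models: MSD estimation, model evaluation/fitting, AICc classification.

test_that("compute_msd matches the worked example and the brute-force oracle", {
  tr <- cell_track("w", x = c(0, 1, 2, 3), y = rep(0, 4), frame_interval = 1)
  cu <- compute_msd(tr)
  expect_equal(cu$msd, c(1, 4, 9))
  expect_equal(cu$lags, c(1, 2, 3))
  expect_equal(cu$n_pairs, c(3, 2, 1))

  still <- cell_track("0", x = rep(0, 5), y = rep(0, 5), frame_interval = 1)
  expect_equal(compute_msd(still)$msd, rep(0, 4))

  # oracle equivalence: exact equality on 50 random tracks of length 5-50
  set.seed(42)
  lens <- sample(5:50, 50, replace = TRUE)
  for (i in seq_along(lens)) {
    tr <- random_track(lens[i], seed = 1000 + i, dt = 2)
    cu <- compute_msd(tr)
    or <- brute_msd(tr$x, tr$y, 2)
    expect_identical(cu$msd, or$msd)
    expect_identical(cu$n_pairs, as.integer(or$n_pairs))
    expect_identical(cu$lags, or$lags)
  }

  expect_error(compute_msd(cell_track("x", x = 0:1, y = 0:1)), "degenerate")
  gappy <- cell_track("g", x = 0:2, y = 0:2, frame = c(0, 1, 3),
                      frame_interval = 1)
  expect_error(compute_msd(gappy), "gaps")
})

test_that("truncate_for_fit keeps the leading 40% with a floor of 4", {
  mk <- function(K) exact_curve("brownian", c(D = 1), K = K, dt = 1)
  expect_equal(truncate_for_fit(mk(19))$fitted_window, 7L)
  expect_equal(truncate_for_fit(mk(100))$fitted_window, 40L)
  expect_equal(truncate_for_fit(mk(5))$fitted_window, 4L)   # clamped
  expect_error(truncate_for_fit(mk(3)), "too short")
})

test_that("eval_msd_model reproduces the closed forms and their limits", {
  expect_equal(eval_msd_model("brownian", c(D = 1), 2), 8)
  # constrained saturates at R^2
  expect_equal(eval_msd_model("constrained", c(Dc = 1, R = 10), 1e6), 100,
               tolerance = 1e-6)
  # constrained initial slope -> 4 Dc
  tau0 <- 1e-6 * 100 / 4
  expect_equal(eval_msd_model("constrained", c(Dc = 1, R = 10), tau0) / tau0,
               4, tolerance = 1e-3)
  # PRW ballistic limit: v^2 tau^2 at small tau
  expect_equal(eval_msd_model("prw", c(v = 2, P = 5), 0.01), 4e-4,
               tolerance = 1e-3)
  # PRW relative error vs v^2 tau^2 < 1% for tau <= P/100
  for (tau in c(0.001, 0.02, 0.05)) {
    got <- eval_msd_model("prw", c(v = 5, P = 10), tau)
    expect_lt(abs(got - 25 * tau^2) / (25 * tau^2), 0.01)
  }
  # PRW diffusive limit: slope within 1% of 2 v^2 P for tau >= 100 P
  m1 <- eval_msd_model("prw", c(v = 5, P = 10), 1000)
  m2 <- eval_msd_model("prw", c(v = 5, P = 10), 1100)
  expect_equal((m2 - m1) / 100, 2 * 25 * 10, tolerance = 0.01)
  # stability across extreme arguments
  ext <- eval_msd_model("prw", c(v = 1, P = 1), c(1e-6, 1e6))
  expect_true(all(is.finite(ext) & ext > 0))
  expect_error(eval_msd_model("brownian", c(D = -1), 1), "positive")
  expect_error(eval_msd_model("powerlaw", c(A = 1, alpha = 2.5), 1), "alpha")
  expect_error(eval_msd_model("brownian", c(D = 1), c(-1, 2)), "lags")
})

test_that("aicc arithmetic, guards, and monotonicity", {
  expect_equal(aicc(10, 10, 1), 2.5)                 # 0 + 2 + 4/8
  expect_equal(aicc(10, 10, 2), 4 + 12 / 7)          # 0 + 4 + 12/7
  expect_error(aicc(10, 3, 2), "n_points")           # denominator 0
  expect_identical(aicc(0, 10, 2), -Inf)
  # strictly increasing in k at fixed rss, n; in rss at fixed n, k
  for (n in c(8, 15, 40)) {
    expect_lt(aicc(5, n, 1), aicc(5, n, 2))
    expect_lt(aicc(2, n, 2), aicc(7, n, 2))
  }
})

test_that("each model recovers its own noiseless curve and wins selection", {
  cases <- list(
    brownian = c(D = 1),
    constrained = c(Dc = 1, R = 10),
    prw = c(v = 5, P = 10),
    powerlaw = c(A = 4, alpha = 1.3))
  for (m in names(cases)) {
    cu <- truncate_for_fit(exact_curve(m, cases[[m]], K = 19, dt = 2))
    fit <- fit_msd_model(cu, m)
    expect_true(fit$converged)
    expect_true(fit$exact_fit)
    expect_equal(unname(fit$params), unname(cases[[m]]), tolerance = 1e-4)
    if (m != "powerlaw") {
      cls <- classify_track(cu)
      expect_identical(cls$best_model, m)
    }
  }
})

test_that("classification of characteristic curves and tie-breaking", {
  # ballistic straight-line track: MSD = v^2 tau^2, only PRW is superlinear
  tr <- cell_track("bal", x = (0:20) * 3, y = rep(0, 21), frame_interval = 1)
  cls <- classify_track(truncate_for_fit(compute_msd(tr)))
  expect_identical(cls$best_model, "prw")
  expect_false(is.na(cls$persistence_speed))
  expect_equal(cls$delta_aicc[["prw"]], 0)
  expect_true(all(cls$delta_aicc >= 0))

  # non-PRW winners leave persistence fields empty
  cu <- truncate_for_fit(exact_curve("brownian", c(D = 2)))
  clb <- classify_track(cu)
  expect_identical(clb$best_model, "brownian")
  expect_true(is.na(clb$persistence_speed))
  expect_true(is.na(clb$persistence_time))
  # rmc is the Brownian-fit D
  expect_equal(clb$rmc, 2, tolerance = 1e-6)
})

test_that("power-law fit is descriptive: alpha tracks the diffusion regime", {
  # exact Brownian curve: alpha = 1, A = 4D
  f1 <- fit_power_law(truncate_for_fit(exact_curve("brownian", c(D = 1))))
  expect_equal(unname(f1$params), c(4, 1), tolerance = 1e-6)
  # ballistic: alpha = 2
  tr <- cell_track("bal", x = (0:20) * 2, y = rep(0, 21), frame_interval = 1)
  f2 <- fit_power_law(truncate_for_fit(compute_msd(tr)))
  expect_equal(f2$params[["alpha"]], 2, tolerance = 1e-4)
  # constrained curve over a window reaching saturation: alpha < 1
  cu <- exact_curve("constrained", c(Dc = 1, R = 6), K = 40, dt = 2)
  cu <- truncate_for_fit(cu, fraction = 1)
  f3 <- fit_power_law(cu)
  expect_lt(f3$params[["alpha"]], 1)
})

test_that("derive_motility maps fits to motility coefficients", {
  clb <- classify_track(truncate_for_fit(exact_curve("brownian", c(D = 1.5))))
  mb <- derive_motility(clb)
  expect_identical(mb$best_model, "brownian")
  expect_equal(mb$rmc, 1.5, tolerance = 1e-6)
  expect_equal(mb$effective_coefficient, 1.5, tolerance = 1e-6)

  clp <- classify_track(truncate_for_fit(
    exact_curve("prw", c(v = 2, P = 3), K = 19, dt = 0.5)))
  mp <- derive_motility(clp)
  expect_identical(mp$best_model, "prw")
  # long-lag slope of the PRW MSD is 2 v^2 P = 4 D_eff -> D_eff = v^2 P / 2
  expect_equal(mp$effective_coefficient, 6, tolerance = 1e-3)
  expect_equal(mp$persistence_speed, 2, tolerance = 1e-3)

  clc <- classify_track(truncate_for_fit(
    exact_curve("constrained", c(Dc = 0.8, R = 8), K = 40, dt = 2)))
  mc <- derive_motility(clc)
  expect_identical(mc$best_model, "constrained")
  expect_equal(mc$effective_coefficient, 0.8, tolerance = 1e-4)
})

test_that("fit preconditions are enforced", {
  cu <- exact_curve("brownian", c(D = 1))
  expect_error(fit_msd_model(cu, "brownian"), "truncate_for_fit")
  tiny <- truncate_for_fit(exact_curve("brownian", c(D = 1), K = 5))
  expect_equal(tiny$fitted_window, 4L)
  expect_s3_class(fit_msd_model(tiny, "prw"), "msd_fit")  # k+2 = 4 points ok
})

test_that("simulation-based recovery sanity (reduced scale)", {
  # smoke-scale version of the ensemble recovery; full scale in acceptance
  co <- simulate_brownian(n_tracks = 60, n_frames = 100, D = 1,
                          frame_interval = 2, seed = 31)
  Ds <- vapply(co$tracks, function(tr)
    fit_msd_model(truncate_for_fit(compute_msd(tr)), "brownian")$params[["D"]],
    numeric(1))
  expect_equal(median(Ds), 1, tolerance = 0.15)

  cp <- simulate_prw(n_tracks = 60, n_frames = 100, v = 5, P = 10,
                     frame_interval = 2, seed = 32)
  cls <- classify_tracks(cp)
  best <- vapply(cls, `[[`, character(1), "best_model")
  expect_gte(mean(best == "prw"), 0.6)
  vs <- vapply(cls[best == "prw"], `[[`, numeric(1), "persistence_speed")
  expect_equal(median(vs), 5, tolerance = 0.2)
})
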