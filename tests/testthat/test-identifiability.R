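test_that("confidence thresholds are chi-squared quantiles", {
  expect_equal(ci_threshold(0.6827, 1), 1.000, tolerance = 1e-3)
  expect_equal(ci_threshold(0.95, 1), 3.841, tolerance = 1e-3)
  expect_equal(ci_threshold(0.95, 20), 31.410, tolerance = 1e-2)
  expect_error(ci_threshold(1.2, 1), "alpha")
  expect_error(ci_threshold(0.95, 0), "df")
})

test_that("linear-Gaussian profile reproduces the closed-form CI", {
  fx <- line_fixture(a_true = 2, times = c(10, 20, 30, 40, 50), sigma = 1,
                     seed = 2)
  fit <- fit_model(fx$data, line_settings(), line_model(),
                   start = c(a = fx$a_hat))
  thr <- c(pointwise = ci_threshold(0.95, 1))
  prof <- profile_likelihood("a", fit, fx$data, thresholds = thr)

  expect_equal(min(abs(prof$delta_chi2)), 0, tolerance = 1e-8)
  expect_gte(min(prof$delta_chi2), -1e-3)
  expect_identical(prof$status, "identifiable")

  expected_half <- sqrt(thr[["pointwise"]]) * fx$se
  ci <- prof$ci[prof$ci$threshold_id == "pointwise", ]
  expect_false(ci$lower_unbounded || ci$upper_unbounded)
  expect_equal(ci$lower, fx$a_hat - expected_half, tolerance = 0.01)
  expect_equal(ci$upper, fx$a_hat + expected_half, tolerance = 0.01)
  expect_true(ci$lower < fit$theta_hat[["a"]] &&
                fit$theta_hat[["a"]] < ci$upper)

  # profile matches the Wald parabola pointwise in the linear case
  parabola <- ((prof$values - fx$a_hat) / fx$se)^2
  expect_equal(prof$delta_chi2, parabola, tolerance = 0.01)
})

test_that("a product-only model is structurally nonidentifiable with log-log
           slope -1", {
  set.seed(7)
  times <- c(5, 10, 20, 40)
  d <- make_data(times, 6 * times + rnorm(4, 0, 0.3), sigma = 0.3)
  # p2's upper bound leaves room for p2 = 6/p1 across the whole p1 box, so
  # the co-fitted parameter never saturates a bound along the profile
  s <- fit_settings(lower = c(p1 = 1e-3, p2 = 1e-3),
                    upper = c(p1 = 1e3, p2 = 1e6),
                    restarts = 3, anneal = list(steps = 30), seed = 11)
  fit <- fit_model(d, s, product_model())
  thr <- c(simultaneous = ci_threshold(0.95, 2))
  prof <- profile_likelihood("p1", fit, d, thresholds = thr,
                             max_steps = 40)
  # flat over the explored range (>= 4 decades)
  expect_gte(log10(max(prof$values) / min(prof$values)), 4)
  expect_lt(max(prof$delta_chi2), 0.01 * thr)
  expect_identical(prof$status, "structurally_nonidentifiable")

  rel <- profile_correlation(prof, "p2")
  expect_equal(rel$slope, -1, tolerance = 0.02)
  products <- prof$values * prof$cofit[, "p2"]
  expect_lt(diff(range(products)) / mean(products), 0.02)
  expect_false(rel$unreliable)
})

test_that("parameters acting on disjoint observables do not correlate", {
  set.seed(8)
  times <- c(5, 10, 20, 40, 80)
  d <- rbind(
    make_data(times, 2 * times + rnorm(5, 0, 0.5), 0.5,
              observable = "pSTAT1_wb"),
    make_data(times, 3 * times + rnorm(5, 0, 0.5), 0.5,
              observable = "SOCS1_mrna"))
  s <- fit_settings(lower = c(q1 = 1e-2, q2 = 1e-2),
                    upper = c(q1 = 1e2, q2 = 1e2),
                    restarts = 2, anneal = list(steps = 20), seed = 3)
  fit <- fit_model(d, s, disjoint_model())
  prof <- profile_likelihood("q1", fit, d,
                             thresholds = c(pt = ci_threshold(0.95, 1)))
  rel <- profile_correlation(prof, "q2")
  expect_lt(abs(rel$slope), 0.05)
})

test_that("one-sided practical nonidentifiability is classified from the
           crossing pattern", {
  # saturating model: y = a * t / (t + b); data only at t >> b leaves b with
  # a finite upper range but flat lower direction within bounds
  sat_model <- prediction_model(function(theta, data) {
    theta[["a"]] * data$time_min / (data$time_min + theta[["b"]])
  })
  set.seed(12)
  times <- c(200, 300, 400, 500)
  d <- make_data(times, 5 * times / (times + 1) + rnorm(4, 0, 0.05), 0.05)
  s <- fit_settings(lower = c(a = 0.1, b = 1e-4),
                    upper = c(a = 100, b = 1e4),
                    restarts = 3, anneal = list(steps = 30), seed = 5)
  fit <- fit_model(d, s, sat_model)
  prof <- profile_likelihood("b", fit, d,
                             thresholds = c(pt = ci_threshold(0.95, 1)),
                             max_steps = 60)
  ci <- prof$ci[1, ]
  expect_identical(prof$status, "practically_nonidentifiable")
  expect_true(ci$lower_unbounded)
  expect_false(ci$upper_unbounded)
})

test_that("pointwise CIs nest inside simultaneous CIs", {
  fx <- line_fixture(a_true = 3, times = seq(10, 60, by = 10), sigma = 0.5,
                     seed = 6)
  fit <- fit_model(fx$data, line_settings(), line_model(),
                   start = c(a = fx$a_hat))
  thr <- c(pointwise = ci_threshold(0.95, 1),
           simultaneous = ci_threshold(0.95, 5))
  prof <- profile_likelihood("a", fit, fx$data, thresholds = thr)
  pw <- prof$ci[prof$ci$threshold_id == "pointwise", ]
  sim <- prof$ci[prof$ci$threshold_id == "simultaneous", ]
  expect_gte(pw$lower, sim$lower)
  expect_lte(pw$upper, sim$upper)
})

test_that("profiles are invariant under walk-direction reversal", {
  # profile twice with mirrored bounds ordering via explicit reversal of the
  # grid: delta_chi2 at matching values agrees within twice the re-anchor
  # tolerance
  fx <- line_fixture(seed = 4)
  fit <- fit_model(fx$data, line_settings(), line_model(),
                   start = c(a = fx$a_hat))
  prof <- profile_likelihood("a", fit, fx$data,
                             thresholds = c(pt = ci_threshold(0.95, 1)))
  redo <- vapply(rev(seq_along(prof$values)), function(i) {
    chi_squared(c(a = prof$values[i]), fx$data, line_model()) - fit$chi2_hat
  }, 0)
  expect_equal(rev(redo), prof$delta_chi2, tolerance = 2e-3)
})

test_that("simultaneous CIs cover the truth at close to nominal rate", {
  a_true <- 2.5
  times <- seq(10, 80, by = 10)
  alpha <- 0.95
  thr <- c(simultaneous = ci_threshold(alpha, 2))
  covered <- vapply(1:50, function(s) {
    fx <- line_fixture(a_true = a_true, times = times, sigma = 1, seed = s)
    fit <- fit_model(fx$data, line_settings(seed = s), line_model(),
                     start = c(a = fx$a_hat))
    prof <- profile_likelihood("a", fit, fx$data, thresholds = thr)
    ci <- prof$ci[1, ]
    ci$lower <= a_true && a_true <= ci$upper
  }, TRUE)
  expect_gte(mean(covered), alpha - 0.10)
})

test_that("trajectory bands envelope the best fit and shrink to it", {
  psc <- make_preset("PSC_like")
  free <- c("k_impD", "k_deph")
  design <- sampling_design(
    times = list(pSTAT1_wb = c(30, 60, 120, 240, 480),
                 ratio_STAT1D_nc = c(60, 180, 420)),
    observables = c("pSTAT1_wb", "ratio_STAT1D_nc"))
  d <- generate_dataset(psc, design, seed = 20)
  s <- pathway_settings(free, psc, restarts = 1, anneal_steps = 10, seed = 2)
  fit <- fit_model(d, s, pathway_prediction_model(psc),
                   start = psc[free])
  prof <- profile_likelihood("k_impD", fit, d,
                             thresholds = c(pt = ci_threshold(0.95, 1)),
                             max_steps = 25)
  times <- seq(0, 540, by = 30)
  band <- trajectory_band(prof, base = psc, what = "STAT1Dn", dose = 100,
                          times = times, n_sets = 5)
  best <- band$members[, "best"]
  expect_true(all(band$lower <= best + 1e-12 & best <= band$upper + 1e-12))

  # a singleton band is the best-fit trajectory with zero width
  single <- trajectory_band(prof, base = psc, what = "STAT1Dn", dose = 100,
                            times = times, n_sets = 1)
  expect_identical(max(single$upper - single$lower), 0)

  path <- withr::local_tempfile(fileext = ".csv")
  write_band(band, path)
  tidy <- read.csv(path)
  expect_identical(names(tidy),
                   c("time_min", "variable", "member_index", "value"))
})

test_that("profiling a fixed parameter is rejected", {
  fx <- line_fixture(seed = 1)
  fit <- fit_model(fx$data, line_settings(), line_model(),
                   start = c(a = fx$a_hat))
  expect_error(profile_likelihood("k_act", fit, fx$data), "not free")
})
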