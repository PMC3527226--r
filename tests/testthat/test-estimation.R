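psc <- make_preset("PSC_like")

test_that("chi-squared matches its definition on hand-built fixtures", {
  # residuals of (1, -0.5, 2) sigmas -> 1 + 0.25 + 4
  d <- make_data(c(10, 20, 30), c(0, 0, 0), sigma = c(2, 4, 1))
  model <- prediction_model(function(theta, data) {
    -c(1, -0.5, 2) * data$sigma
  })
  expect_equal(chi_squared(c(a = 0), d, model), 5.25, tolerance = 1e-12)

  # single record 2 sigmas away -> 4
  d1 <- make_data(5, 10 + 2 * 0.5, sigma = 0.5)
  m1 <- prediction_model(function(theta, data) rep(10, nrow(data)))
  expect_equal(chi_squared(c(a = 1), d1, m1), 4, tolerance = 1e-12)

  # noise-free data from the same parameters -> chi2 exactly 0 (the model
  # re-simulates deterministically)
  d0 <- generate_dataset(psc, sampling_design(), seed = 2)
  d0$value <- pathway_prediction_model(psc)$predict(psc, d0)
  expect_lt(chi_squared(psc, d0), 1e-12)
})

test_that("undefined observables raise an error, never a silent skip", {
  d <- make_data(c(0, 30), c(1, 1), sigma = 1, observable = "ratio_STAT1D_nc")
  model <- pathway_prediction_model(psc)
  expect_error(chi_squared(psc[0], d, model), "undefined")
})

test_that("fit recovers the minimum of a separable quadratic surrogate", {
  target <- c(a = 3.2, b = 0.57, c = 12)
  d <- make_data(c(1, 2, 3), as.numeric(target), sigma = 1)
  model <- prediction_model(function(theta, data) {
    as.numeric(theta[c("a", "b", "c")])
  })
  s <- fit_settings(lower = c(a = 0.1, b = 0.01, c = 1),
                    upper = c(a = 50, b = 10, c = 100),
                    restarts = 3, anneal = list(steps = 20), seed = 4)
  fit <- fit_model(d, s, model)
  expect_lt(max(abs(fit$theta_hat - target)), 1e-5)
  expect_lt(fit$chi2_hat, 1e-10)
  expect_s3_class(fit$restarts, "data.frame")
  expect_equal(fit$chi2_hat, min(fit$restarts$end_cost))
})

test_that("a fit started at the optimum stays there", {
  fx <- line_fixture(seed = 3)
  fit <- fit_model(fx$data, line_settings(), line_model(),
                   start = c(a = fx$a_hat))
  expect_equal(fit$theta_hat[["a"]], fx$a_hat, tolerance = 1e-6)
  expect_lte(fit$chi2_hat,
             chi_squared(c(a = fx$a_hat), fx$data, line_model()) + 1e-10)
})

test_that("multistart never ends above its start cost", {
  fx <- line_fixture(seed = 9)
  fit <- fit_model(fx$data, line_settings(restarts = 5, seed = 2),
                   line_model())
  expect_true(all(fit$restarts$end_cost <= fit$restarts$start_cost + 1e-9))
  expect_true(all(fit$restarts$end_cost <= fit$restarts$anneal_cost + 1e-9))
})

test_that("pathway fit on noise-free data reaches the generating optimum", {
  free <- c("k_act", "k_impD", "k_deph")
  design <- sampling_design(
    times = list(pSTAT1_wb = c(15, 30, 60, 120, 240, 480),
                 ratio_STAT1D_nc = c(30, 60, 120, 240, 480)),
    observables = c("pSTAT1_wb", "ratio_STAT1D_nc"), sigma = 0.05)
  d <- generate_dataset(psc, design, seed = 10)
  # tight integrator tolerances so finite-difference gradients near the
  # optimum are not dominated by adaptive-step noise
  mdl <- pathway_prediction_model(psc,
                                  sim_args = list(rtol = 1e-10, atol = 1e-12))
  d$value <- mdl$predict(psc, d) # strip the noise
  s <- pathway_settings(free, psc, restarts = 2, anneal_steps = 25, seed = 6)
  fit <- fit_model(d, s, mdl)
  truth_cost <- chi_squared(psc[free], d, mdl)
  expect_lte(fit$chi2_hat, truth_cost + 1e-6)
  expect_equal(fit$theta_hat, psc[free], tolerance = 1e-3)
})

test_that("fit is equivariant under joint rescaling of scaling factor and
           data", {
  free <- c("k_phos", "s_pstat")
  design <- sampling_design(times = list(pSTAT1_wb = c(30, 60, 120, 240)),
                            observables = "pSTAT1_wb", sigma = 0.1)
  d <- generate_dataset(psc, design, seed = 12)
  mdl <- pathway_prediction_model(psc,
                                  sim_args = list(rtol = 1e-10, atol = 1e-12))
  s <- pathway_settings(free, psc, restarts = 1, anneal_steps = 15, seed = 2)
  fit1 <- fit_model(d, s, mdl)
  d2 <- d; d2$value <- 3 * d2$value; d2$sigma <- 3 * d2$sigma
  s2 <- s
  s2$lower[["s_pstat"]] <- 3 * s2$lower[["s_pstat"]]
  s2$upper[["s_pstat"]] <- 3 * s2$upper[["s_pstat"]]
  fit2 <- fit_model(d2, s2, mdl)
  expect_equal(fit2$chi2_hat, fit1$chi2_hat, tolerance = 1e-4)
  expect_equal(fit2$theta_hat[["s_pstat"]] / fit1$theta_hat[["s_pstat"]], 3,
               tolerance = 1e-3)
  expect_equal(fit2$theta_hat[["k_phos"]], fit1$theta_hat[["k_phos"]],
               tolerance = 1e-3)
})

test_that("fits on noisy data land in the chi-squared sanity band", {
  # chi2(theta_hat) <= N with >= 50% probability across seeds
  hits <- vapply(1:20, function(s) {
    fx <- line_fixture(a_true = 1.5, times = seq(10, 100, by = 10),
                       sigma = 0.8, seed = s)
    fit <- fit_model(fx$data, line_settings(seed = s), line_model())
    fit$chi2_hat <= nrow(fx$data)
  }, TRUE)
  expect_gte(mean(hits), 0.5)
})

test_that("settings validation rejects malformed bounds", {
  expect_error(fit_settings(lower = c(a = 1), upper = c(a = 1)), "lower")
  expect_error(fit_settings(lower = c(a = 2), upper = c(a = 1)), "lower")
  expect_error(fit_settings(lower = c(a = 1), upper = c(a = 2), restarts = 0),
               "restarts")
  expect_error(fit_settings(lower = c(a = 0), upper = c(a = 1)),
               "positive lower")
})

test_that("fit results serialize with full restart provenance", {
  fx <- line_fixture(seed = 5)
  fit <- fit_model(fx$data, line_settings(restarts = 3, seed = 1),
                   line_model())
  path <- withr::local_tempfile(fileext = ".json")
  write_fit_result(fit, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$chi2_hat, fit$chi2_hat)
  expect_equal(nrow(back$restarts), 3)
})
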