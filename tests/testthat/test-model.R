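psc <- make_preset("PSC_like")

test_that("basal steady state balances synthesis and degradation", {
  p <- psc
  p[["b_m_stat"]] <- 0.2; p[["d_m_stat"]] <- 0.1
  p[c("stat1_uc0", "stat1_un0")] <- consistent_initial_stat1(p)
  y0 <- basal_steady_state(pathway_parameters(p))
  expect_equal(y0[["mSTAT1"]], 2.0)

  # all synthesis and initial conditions zero -> zero vector, exact rest
  z <- psc
  z[c("b_m_stat", "k_tl_stat", "stat1_uc0", "stat1_un0")] <- 0
  y0 <- basal_steady_state(pathway_parameters(z))
  expect_true(all(y0 == 0))
  expect_equal(attr(y0, "rhs_norm"), 0)

  # presets ship consistent initial conditions
  for (ct in c("PSC_like", "PC_like")) {
    y0 <- basal_steady_state(make_preset(ct))
    expect_lt(attr(y0, "rhs_norm"), 1e-8)
  }

  # positive synthesis with no degradation has no finite rest state
  bad <- psc; bad[["d_m_stat"]] <- 0
  expect_error(basal_steady_state(pathway_parameters(bad)), "no finite basal")
})

test_that("unstimulated system stays at the basal state", {
  tr <- simulate_pathway(psc, dose = 0, times = seq(0, 540, by = 20))
  y0 <- basal_steady_state(psc)
  drift <- max(abs(sweep(tr$states, 2, as.numeric(y0))))
  expect_lt(drift, 1e-6 * max(1, max(abs(y0))))
})

test_that("receptor subsystem reproduces its closed form", {
  p <- psc
  p[["k_inact"]] <- 0
  tr <- simulate_pathway(pathway_parameters(p), dose = 100,
                         times = seq(0, 300, by = 5))
  expected <- p[["R_tot"]] * (1 - exp(-p[["k_act"]] * 100 * tr$time))
  expect_equal(tr$states[, "IIr"], expected, tolerance = 1e-6)
  expect_lt(abs(tr$states[nrow(tr$states), "IIr"] - p[["R_tot"]]), 1e-4)
})

test_that("dual integrators agree on the full stiff trajectory", {
  times <- seq(0, 540, by = 10)
  a <- simulate_pathway(psc, 100, times, dede_method = "adams",
                        rtol = 1e-10, atol = 1e-12)
  b <- simulate_pathway(psc, 100, times, dede_method = "bdf",
                        rtol = 1e-10, atol = 1e-12)
  scale <- pmax(abs(a$states), 1e-6)
  expect_lt(max(abs(a$states - b$states) / scale), 1e-6)
})

test_that("total STAT1 is conserved without synthesis and turnover", {
  p <- psc
  p[c("b_m_stat", "k_tl_stat", "d_stat")] <- 0
  p[c("stat1_uc0", "stat1_un0")] <- c(5, 1)
  tr <- simulate_pathway(pathway_parameters(p), 100, seq(0, 540, by = 10))
  tot <- rowSums(tr$states[, c("STAT1Uc", "STAT1Un", "STAT1Dc", "STAT1Dn")])
  expect_lt(diff(range(tot)) / tot[1], 1e-6)
})

test_that("states stay non-negative across random parameter draws", {
  set.seed(11)
  for (k in 1:8) {
    p <- psc
    rates <- setdiff(pathway_parameter_names,
                     c("tau_socs", "tau_stat", "s_pstat", "s_stat", "s_socs",
                       "stat1_uc0", "stat1_un0"))
    p[rates] <- as.numeric(p[rates]) * 10^runif(length(rates), -1, 1)
    p[c("tau_socs", "tau_stat")] <- runif(2, 0, 90)
    p[c("stat1_uc0", "stat1_un0")] <- runif(2, 0, 10)
    tr <- simulate_pathway(pathway_parameters(p), dose = 100,
                           times = seq(0, 540, by = 20))
    expect_true(all(tr$states >= 0))
  }
})

test_that("receptor response is monotone in dose", {
  times <- seq(0, 540, by = 20)
  lo <- simulate_pathway(psc, 20, times)
  hi <- simulate_pathway(psc, 100, times)
  expect_true(all(hi$states[, "IIr"] >= lo$states[, "IIr"] - 1e-10))
})

test_that("zero delays reduce to the plain-ODE limit", {
  p <- psc
  p[c("tau_socs", "tau_stat")] <- 0
  p <- pathway_parameters(p)
  times <- seq(0, 540, by = 10)
  dd <- simulate_pathway(p, 100, times, method = "dede")
  lc <- simulate_pathway(p, 100, times, method = "linchain")
  scale <- pmax(abs(dd$states), 1e-6)
  expect_lt(max(abs(dd$states - lc$states) / scale), 1e-6)
})

test_that("linear-chain delay approximation matches interpolated history", {
  times <- seq(0, 540, by = 10)
  dd <- simulate_pathway(psc, 100, times)
  lc <- simulate_pathway(psc, 100, times, method = "linchain",
                         chain_order = 40L)
  rel <- vapply(colnames(dd$states), function(j) {
    max(abs(dd$states[, j] - lc$states[, j])) / max(abs(dd$states[, j]))
  }, 0)
  expect_lt(max(rel), 0.02)
})

test_that("time grids not starting at stimulation are rejected", {
  expect_error(simulate_pathway(psc, 100, times = c(10, 20, 30)), "start at 0")
  expect_error(simulate_pathway(psc, 100, times = c(0, 10, 10)), "increasing")
})

test_that("observation map scales and ratios behave", {
  tr <- simulate_pathway(psc, 100, seq(0, 540, by = 10))
  obs <- observe(tr)

  # unit scaling: pSTAT1_wb = s_pstat * (Dc + Dn)
  i <- 10
  expect_equal(obs$pSTAT1_wb[i],
               unname(psc[["s_pstat"]] *
                        (tr$states[i, "STAT1Dc"] + tr$states[i, "STAT1Dn"])))
  p2 <- psc; p2[["s_pstat"]] <- 7
  expect_equal(observe(tr, pathway_parameters(p2))$pSTAT1_wb,
               7 * obs$pSTAT1_wb)

  # ratio observables invariant under rescaling all STAT1 species
  tr7 <- tr
  stat_cols <- c("STAT1Uc", "STAT1Dc", "STAT1Dn", "STAT1Un")
  tr7$states[, stat_cols] <- 7 * tr7$states[, stat_cols]
  obs7 <- observe(tr7)
  expect_equal(obs7$ratio_STAT1_nc, obs$ratio_STAT1_nc)
  expect_equal(obs7$ratio_STAT1D_nc, obs$ratio_STAT1D_nc)

  # undefined ratio flagged, not raised: t = 0 has empty phospho pools
  expect_true(is.na(obs$ratio_STAT1D_nc[1]))
})

test_that("late-time phospho N/C ratio reaches the import/dephosphorylation
           balance", {
  tr <- simulate_pathway(psc, 100, seq(0, 540, by = 5))
  obs <- observe(tr)
  late <- obs$time_min >= 450
  expected <- psc[["k_impD"]] / psc[["k_deph"]]
  expect_lt(max(abs(obs$ratio_STAT1D_nc[late] - expected)) / expected, 0.05)
})

test_that("trajectory CSV export is tidy", {
  tr <- simulate_pathway(psc, 100, seq(0, 60, by = 20))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(tr, path, what = "observables")
  tidy <- read.csv(path)
  expect_identical(names(tidy), c("time_min", "variable", "value",
                                  "dose_ng_ml"))
  expect_setequal(unique(tidy$variable), observable_names)
  expect_true(all(tidy$dose_ng_ml == 100))
})
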