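#' State variable names of the STAT1 pathway model
#'
#' `IIr` is the active type II IFN receptor complex (JAKs lumped in),
#' `STAT1Uc`/`STAT1Un` unphosphorylated STAT1 in cytoplasm/nucleus,
#' `STAT1Dc`/`STAT1Dn` phosphorylated STAT1 in cytoplasm/nucleus (counted in
#' monomer equivalents), `mSTAT1`/`mSOCS1` the two mRNAs and `SOCS1` the
#' feedback protein. All concentrations in arbitrary units.
#'
#' @format Character vector of length 8.
#' @export
pathway_state_names <- c("IIr", "STAT1Uc", "STAT1Dc", "STAT1Dn", "STAT1Un",
                         "mSTAT1", "mSOCS1", "SOCS1")

.STATE_IDX <- stats::setNames(seq_along(pathway_state_names), pathway_state_names)

#' Right-hand side of the delay-ODE system
#'
#' Exposed so that alternative model variants can reuse or replace it without
#' touching the estimation / identifiability / sensitivity machinery, which
#' only consume trajectories and observables.
#'
#' Reactions: IFN-gamma activates the receptor (mass action on free receptor,
#' first-order deactivation); receptor-bound kinases phosphorylate cytosolic
#' STAT1 with the flux inhibited by SOCS1 through the saturating factor
#' 1/(1 + k_inh * SOCS1); phospho-STAT1 shuttles to the nucleus, is
#' dephosphorylated there, and the unphosphorylated protein is exported;
#' unphosphorylated STAT1 also shuttles in; nuclear phospho-STAT1 drives
#' delayed transcription of SOCS1 and STAT1 itself.
#'
#' @param t Time, minutes.
#' @param y Named state vector (see [pathway_state_names]).
#' @param parms List with elements `p` (parameter vector), `dose` (ng/ml),
#'   `basal` (history state for t < 0), `feedback` ("protein" or "mrna"),
#'   and `lag_fun(t, tau, idx, channel)` returning the lagged value of state
#'   `idx`; `channel` ("stat" or "socs") names the delay term requesting it.
#' @return List whose first element is the derivative vector.
#' @export
pathway_rhs <- function(t, y, parms) {
  p <- parms$p
  lag_Dn <- function(tau, channel)
    parms$lag_fun(t, tau, .STATE_IDX[["STAT1Dn"]], channel)
  inhibitor <- if (identical(parms$feedback, "mrna")) y[[7L]] else y[[8L]]
  flux <- p[["k_phos"]] * y[[1L]] * y[[2L]] / (1 + p[["k_inh"]] * inhibitor)
  dIIr <- p[["k_act"]] * parms$dose * (p[["R_tot"]] - y[[1L]]) -
    p[["k_inact"]] * y[[1L]]
  dUc <- -flux - p[["k_impU"]] * y[[2L]] + p[["k_exp"]] * y[[5L]] +
    p[["k_tl_stat"]] * y[[6L]] - p[["d_stat"]] * y[[2L]]
  dDc <- flux - p[["k_impD"]] * y[[3L]]
  dDn <- p[["k_impD"]] * y[[3L]] - p[["k_deph"]] * y[[4L]]
  dUn <- p[["k_deph"]] * y[[4L]] + p[["k_impU"]] * y[[2L]] -
    p[["k_exp"]] * y[[5L]] - p[["d_stat"]] * y[[5L]]
  dmSTAT <- p[["b_m_stat"]] + p[["k_tc_stat"]] * lag_Dn(p[["tau_stat"]], "stat") -
    p[["d_m_stat"]] * y[[6L]]
  dmSOCS <- p[["k_tc_socs"]] * lag_Dn(p[["tau_socs"]], "socs") -
    p[["d_m_socs"]] * y[[7L]]
  dSOCS <- p[["k_tl_socs"]] * y[[7L]] - p[["d_socs"]] * y[[8L]]
  list(c(dIIr, dUc, dDc, dDn, dUn, dmSTAT, dmSOCS, dSOCS))
}

# lag accessor for dede(): basal history before the lag horizon
.lag_dede <- function(t, tau, idx, basal) {
  if (tau <= 0) return(NA_real_) # caller substitutes current value
  if (t <= tau) basal[[idx]] else deSolve::lagvalue(t - tau, idx)
}

#' Pre-stimulus basal steady state
#'
#' The unstimulated resting state: no active receptor, no phosphorylated
#' STAT1, no SOCS1 mRNA or protein, STAT1 mRNA at its synthesis/degradation
#' balance and unphosphorylated STAT1 pools at the supplied initial
#' conditions. The residual norm of the right-hand side at the returned state
#' is attached as attribute `"rhs_norm"`; it is ~0 only when `stat1_uc0` /
#' `stat1_un0` are consistent with STAT1 synthesis and turnover (see
#' [consistent_initial_stat1()]).
#'
#' @param params Parameter set.
#' @return Named state vector with attribute `rhs_norm`.
#' @export
basal_steady_state <- function(params) {
  validate_parameters(params)
  if (params[["b_m_stat"]] > 0 && params[["d_m_stat"]] <= 0) {
    stop("no finite basal state: positive STAT1 mRNA synthesis with ",
         "nonpositive degradation rate")
  }
  m0 <- if (params[["b_m_stat"]] == 0) 0 else
    params[["b_m_stat"]] / params[["d_m_stat"]]
  y0 <- stats::setNames(numeric(8), pathway_state_names)
  y0[["mSTAT1"]] <- m0
  y0[["STAT1Uc"]] <- params[["stat1_uc0"]]
  y0[["STAT1Un"]] <- params[["stat1_un0"]]
  parms <- list(p = params, dose = 0, basal = y0, feedback = "protein",
                lag_fun = function(t, tau, idx, channel) y0[[idx]])
  d <- pathway_rhs(0, y0, parms)[[1L]]
  attr(y0, "rhs_norm") <- sqrt(sum(d^2))
  y0
}

#' Initial STAT1 pools consistent with synthesis and turnover
#'
#' Solves the linear balance of translation, turnover and nucleocytoplasmic
#' shuttling of unphosphorylated STAT1 at dose 0, returning `stat1_uc0` and
#' `stat1_un0` such that the basal state is an exact steady state.
#'
#' @param params Parameter set (its `stat1_uc0`/`stat1_un0` entries are
#'   ignored).
#' @return Named numeric vector `c(stat1_uc0, stat1_un0)`.
#' @export
consistent_initial_stat1 <- function(params) {
  m0 <- if (params[["b_m_stat"]] == 0) 0 else
    params[["b_m_stat"]] / params[["d_m_stat"]]
  synth <- params[["k_tl_stat"]] * m0
  kiu <- params[["k_impU"]]; kex <- params[["k_exp"]]; dst <- params[["d_stat"]]
  if (synth == 0) return(c(stat1_uc0 = 0, stat1_un0 = 0))
  if (dst <= 0) {
    stop("no finite basal state: positive STAT1 synthesis with zero turnover")
  }
  # Un balance: kiu*Uc = (kex + dst)*Un; Uc balance: synth = (dst+kiu)*Uc - kex*Un
  denom <- dst + kiu - kex * kiu / (kex + dst)
  uc0 <- synth / denom
  un0 <- kiu * uc0 / (kex + dst)
  c(stat1_uc0 = uc0, stat1_un0 = un0)
}

#' Simulate the STAT1 pathway
#'
#' Integrates the delay-ODE system from the basal state with the basal state
#' as history for t < 0. Two integration routes are available: `"dede"`
#' (default; interpolated-history delay integration via [deSolve::dede()])
#' and `"linchain"` (linear-chain approximation of the two transcriptional
#' delays by `chain_order` first-order stages each, integrated as a plain
#' ODE) which serves as an independent cross-check.
#'
#' @param params Parameter set.
#' @param dose IFN-gamma dose, ng/ml.
#' @param times Time grid in minutes, strictly increasing, starting at 0.
#' @param method `"dede"` or `"linchain"`.
#' @param rtol,atol Integration tolerances.
#' @param chain_order Number of stages per delay for `"linchain"`.
#' @param dede_method Sub-method passed to [deSolve::dede()] (e.g. `"lsoda"`,
#'   `"adams"`, `"bdf"`); useful for dual-integrator checks.
#' @param feedback Whether SOCS1 protein (default) or SOCS1 mRNA inhibits
#'   phosphorylation.
#' @return Object of class `state_trajectory`: list with `time`, `states`
#'   (matrix, one column per state), `dose`, `params`.
#' @export
simulate_pathway <- function(params, dose, times = seq(0, 540, by = 3),
                             method = c("dede", "linchain"),
                             rtol = 1e-8, atol = 1e-10, chain_order = 20L,
                             dede_method = "lsoda",
                             feedback = c("protein", "mrna")) {
  method <- match.arg(method)
  feedback <- match.arg(feedback)
  validate_parameters(params)
  if (dose < 0) stop("dose must be >= 0")
  if (length(times) < 2 || times[1] != 0 || any(diff(times) <= 0)) {
    stop("time grid must start at 0 (stimulation time) and be strictly increasing")
  }
  y0 <- basal_steady_state(params)
  out <- if (method == "dede") {
    .simulate_dede(params, dose, times, y0, rtol, atol, dede_method, feedback)
  } else {
    .simulate_linchain(params, dose, times, y0, rtol, atol, chain_order,
                       feedback)
  }
  if (anyNA(out) || nrow(out) != length(times)) {
    stop("integration failed: solver returned ",
         nrow(out), "/", length(times), " time points",
         if (anyNA(out)) " with NA values" else "")
  }
  states <- unname(as.matrix(out[, 1L + seq_len(8L), drop = FALSE]))
  colnames(states) <- pathway_state_names
  neg <- min(states)
  if (neg < -1e-8 * max(1, max(abs(states)))) {
    stop(sprintf("integration failed: negative state beyond tolerance (min %.3g)",
                 neg))
  }
  states[states < 0] <- 0
  structure(list(time = as.numeric(times), states = states, dose = dose,
                 params = params),
            class = "state_trajectory")
}

.simulate_dede <- function(params, dose, times, y0, rtol, atol, dede_method,
                           feedback) {
  basal <- as.numeric(y0)
  parms <- list(p = params, dose = dose, basal = basal, feedback = feedback,
                lag_fun = NULL)
  rhs <- function(t, y, parms) {
    parms$lag_fun <- function(t, tau, idx, channel) {
      v <- .lag_dede(t, tau, idx, basal)
      if (is.na(v)) y[[idx]] else v
    }
    pathway_rhs(t, y, parms)
  }
  as.data.frame(deSolve::dede(y = as.numeric(y0), times = times, func = rhs,
                              parms = parms, method = dede_method,
                              rtol = rtol, atol = atol))
}

.simulate_linchain <- function(params, dose, times, y0, rtol, atol, n, feedback) {
  n <- as.integer(n)
  basal_Dn <- y0[["STAT1Dn"]]
  # two chains relaying STAT1Dn with total delay tau_socs / tau_stat
  taus <- c(params[["tau_socs"]], params[["tau_stat"]])
  aug0 <- c(as.numeric(y0), rep(basal_Dn, 2L * n))
  rhs <- function(t, y, parms) {
    core <- y[1:8]
    c1 <- y[8L + seq_len(n)]
    c2 <- y[8L + n + seq_len(n)]
    lagged <- c(socs = if (taus[1] <= 0) core[4L] else c1[n],
                stat = if (taus[2] <= 0) core[4L] else c2[n])
    parms$lag_fun <- function(t, tau, idx, channel) lagged[[channel]]
    dcore <- pathway_rhs(t, core, parms)[[1L]]
    dchain <- function(chain, tau) {
      if (tau <= 0) return(rep(0, n))
      r <- n / tau
      r * (c(core[4L], chain[-n]) - chain)
    }
    list(c(dcore, dchain(c1, taus[1]), dchain(c2, taus[2])))
  }
  parms <- list(p = params, dose = dose, basal = as.numeric(y0),
                feedback = feedback)
  out <- as.data.frame(deSolve::ode(y = aug0, times = times, func = rhs,
                                    parms = parms, rtol = rtol, atol = atol))
  out[, 1:9]
}

#' @export
print.state_trajectory <- function(x, ...) {
  cat("<state_trajectory>", length(x$time), "time points over [",
      x$time[1], ",", max(x$time), "] min, dose", x$dose, "ng/ml\n")
  invisible(x)
}

#' Observable names produced by the observation map
#' @format Character vector of length 5.
#' @export
observable_names <- c("pSTAT1_wb", "STAT1_wb", "SOCS1_mrna",
                      "ratio_STAT1_nc", "ratio_STAT1D_nc")

#' Map a trajectory to the measured observables
#'
#' Immunoblot observables are scaled sums of model species (phospho-STAT1:
#' cytoplasmic + nuclear phosphorylated pools; total STAT1: all four protein
#' pools; SOCS1 mRNA), the immunofluorescence observables are the
#' nuclear:cytoplasmic ratios of total and phosphorylated STAT1. Ratio
#' denominators below `eps` (1e-9 a.u.) mark that observable `NA`
#' (undefined) at that time point rather than raising an error.
#'
#' @param traj `state_trajectory`.
#' @param params Parameter set supplying the scaling factors; defaults to the
#'   trajectory's own parameters.
#' @param eps Denominator cutoff, a.u.
#' @return Data frame with column `time_min` and one column per observable.
#' @export
observe <- function(traj, params = traj$params, eps = 1e-9) {
  s <- traj$states
  num_tot <- s[, "STAT1Dn"] + s[, "STAT1Un"]
  den_tot <- s[, "STAT1Dc"] + s[, "STAT1Uc"]
  ratio_tot <- ifelse(den_tot < eps, NA_real_, num_tot / den_tot)
  ratio_p <- ifelse(s[, "STAT1Dc"] < eps, NA_real_,
                    s[, "STAT1Dn"] / s[, "STAT1Dc"])
  data.frame(
    time_min = traj$time,
    pSTAT1_wb = params[["s_pstat"]] * (s[, "STAT1Dc"] + s[, "STAT1Dn"]),
    STAT1_wb = params[["s_stat"]] *
      (s[, "STAT1Uc"] + s[, "STAT1Un"] + s[, "STAT1Dc"] + s[, "STAT1Dn"]),
    SOCS1_mrna = params[["s_socs"]] * s[, "mSOCS1"],
    ratio_STAT1_nc = ratio_tot,
    ratio_STAT1D_nc = ratio_p
  )
}

#' Write a trajectory (or its observables) as tidy CSV
#'
#' Columns: `time_min`, `variable`, `value`, `dose_ng_ml`.
#'
#' @param traj `state_trajectory`.
#' @param path Output file.
#' @param what `"states"` or `"observables"`.
#' @export
write_trajectory <- function(traj, path, what = c("states", "observables")) {
  what <- match.arg(what)
  wide <- if (what == "states") {
    cbind(data.frame(time_min = traj$time), as.data.frame(traj$states))
  } else {
    obs <- observe(traj)
    names(obs)[1] <- "time_min"
    obs
  }
  vars <- setdiff(names(wide), "time_min")
  tidy <- do.call(rbind, lapply(vars, function(v) {
    data.frame(time_min = wide$time_min, variable = v, value = wide[[v]],
               dose_ng_ml = traj$dose)
  }))
  utils::write.csv(tidy, path, row.names = FALSE)
  invisible(path)
}
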