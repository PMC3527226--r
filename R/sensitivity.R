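#' Time-dependent metabolic control coefficient
#'
#' Relative response of a state variable (or observable) to a relative
#' perturbation of one parameter at finite times: the system is simulated
#' unperturbed and with `p -> p * (1 + delta)` (default -1%), and the
#' coefficient `(delta x / x) / (delta p / p)` is returned per time point —
#' the one-sided finite-difference realization of the time-dependent control
#' coefficient. Time points where the unperturbed variable is below `eps`
#' are masked (`NA`), never interpolated; with the default output `STAT1Dn`
#' that always masks t = 0 (empty phospho pools before stimulation).
#'
#' @param params Parameter set.
#' @param parameter_id Perturbed parameter (value must be > 0).
#' @param variable_id State variable or observable name (default `STAT1Dn`,
#'   nuclear phospho-STAT1, the pathway output).
#' @param dose Dose, ng/ml.
#' @param times Time grid, min.
#' @param delta Relative perturbation, non-zero, |delta| < 1 (default -0.01).
#' @param eps Denominator cutoff, a.u.
#' @param sim_args Extra arguments for [simulate_pathway()].
#' @return Object of class `control_coefficients`: `time`, `coefficient`
#'   (NA where masked), `parameter_id`, `variable_id`, `delta`.
#' @export
mcc <- function(params, parameter_id, variable_id = "STAT1Dn", dose = 100,
                times = seq(0, 540, by = 10), delta = -0.01, eps = 1e-9,
                sim_args = list()) {
  if (delta == 0 || abs(delta) >= 1) stop("delta must be non-zero with |delta| < 1")
  if (!parameter_id %in% pathway_parameter_names) {
    stop("unknown parameter: ", parameter_id)
  }
  if (params[[parameter_id]] <= 0) stop("perturbed parameter must be > 0")
  extract <- function(p) {
    traj <- do.call(simulate_pathway,
                    c(list(params = p, dose = dose, times = times), sim_args))
    if (variable_id %in% pathway_state_names) {
      traj$states[, variable_id]
    } else if (variable_id %in% observable_names) {
      observe(traj, p)[[variable_id]]
    } else stop("unknown variable or observable: ", variable_id)
  }
  x0 <- extract(pathway_parameters(params))
  pp <- params
  pp[parameter_id] <- pp[[parameter_id]] * (1 + delta)
  x1 <- extract(pathway_parameters(pp))
  coef <- ifelse(abs(x0) < eps, NA_real_, (x1 - x0) / x0 / delta)
  structure(list(time = times, coefficient = coef,
                 parameter_id = parameter_id, variable_id = variable_id,
                 delta = delta, dose = dose),
            class = "control_coefficients")
}

#' @export
print.control_coefficients <- function(x, ...) {
  cat("<control_coefficients>", x$parameter_id, "on", x$variable_id,
      "| range", format(range(x$coefficient, na.rm = TRUE)), "\n")
  invisible(x)
}

#' Control-coefficient band over a parameter's confidence interval
#'
#' Computes [mcc()] for `n_sets` parameter vectors spaced evenly along the
#' in-CI portion of the parameter's likelihood profile (profiled value plus
#' its co-fitted partners, remaining parameters at the best fit) and returns
#' the per-time envelope together with the default-set coefficient.
#'
#' @param profile `likelihood_profile` of the perturbed parameter.
#' @param base Full parameter vector for parameters outside the fit.
#' @param variable_id,dose,times,delta,eps,sim_args As in [mcc()].
#' @param n_sets Number of CI-covering parameter sets (default 20).
#' @param threshold Chi-squared threshold delimiting the in-CI portion.
#' @return `control_coefficients` with additional fields `band_lower`,
#'   `band_upper`, `members` (matrix of per-set coefficients).
#' @export
mcc_band <- function(profile, base, variable_id = "STAT1Dn", dose = 100,
                     times = seq(0, 540, by = 10), n_sets = 20L,
                     delta = -0.01, eps = 1e-9,
                     threshold = max(profile$thresholds), sim_args = list()) {
  inci <- which(profile$delta_chi2 <= threshold)
  if (length(inci) == 0) stop("no grid points inside the confidence interval")
  pick <- inci[unique(round(seq(1, length(inci), length.out = min(n_sets, length(inci)))))]
  param_set <- function(i) {
    theta <- profile$theta_hat
    theta[profile$parameter_id] <- profile$values[i]
    if (ncol(profile$cofit) > 0) theta[colnames(profile$cofit)] <- profile$cofit[i, ]
    pathway_parameters(replace(base, names(theta), theta))
  }
  members <- sapply(pick, function(i) {
    mcc(param_set(i), profile$parameter_id, variable_id, dose, times, delta,
        eps, sim_args)$coefficient
  })
  default <- mcc(pathway_parameters(replace(base, names(profile$theta_hat),
                                            profile$theta_hat)),
                 profile$parameter_id, variable_id, dose, times, delta, eps,
                 sim_args)
  members <- cbind(members, default = default$coefficient)
  out <- default
  out$members <- members
  out$band_lower <- suppressWarnings(apply(members, 1, min, na.rm = TRUE))
  out$band_upper <- suppressWarnings(apply(members, 1, max, na.rm = TRUE))
  out$band_lower[!is.finite(out$band_lower)] <- NA_real_
  out$band_upper[!is.finite(out$band_upper)] <- NA_real_
  out
}

#' Finite-fraction inhibition simulation
#'
#' Simulates the model with one parameter scaled by `(1 - fraction)` (e.g.
#' 0.5 for 50% inhibition) and returns both trajectories plus the per-time
#' relative change of a chosen variable — the finite-perturbation companion
#' to the -1% control coefficients.
#'
#' @param params Parameter set.
#' @param parameter_id Inhibited parameter.
#' @param fraction Inhibition fraction in [0, 1).
#' @param dose Dose, ng/ml.
#' @param times Time grid, min.
#' @param variable_id Variable whose relative change is reported.
#' @param eps Denominator cutoff.
#' @param sim_args Extra arguments for [simulate_pathway()].
#' @return List: `default` and `inhibited` (`state_trajectory`), `time`,
#'   `relative_change` (NA where the default variable is below `eps`).
#' @export
inhibition_sim <- function(params, parameter_id, fraction, dose = 100,
                           times = seq(0, 540, by = 5),
                           variable_id = "STAT1Dn", eps = 1e-9,
                           sim_args = list()) {
  if (fraction < 0 || fraction >= 1) stop("fraction must be in [0, 1)")
  p1 <- params
  p1[parameter_id] <- p1[[parameter_id]] * (1 - fraction)
  tr0 <- do.call(simulate_pathway,
                 c(list(params = pathway_parameters(params), dose = dose,
                        times = times), sim_args))
  tr1 <- do.call(simulate_pathway,
                 c(list(params = pathway_parameters(p1), dose = dose,
                        times = times), sim_args))
  x0 <- tr0$states[, variable_id]
  x1 <- tr1$states[, variable_id]
  list(default = tr0, inhibited = tr1, time = times,
       relative_change = ifelse(abs(x0) < eps, NA_real_, (x1 - x0) / x0))
}

#' Forward-sensitivity control coefficients (augmented-system reference)
#'
#' Integrates the delay system augmented with the sensitivity equations
#' `s' = (df/dy) s + (df/dy_lag) s_lag + df/dp` (Jacobians by central finite
#' differences of the right-hand side, lagged sensitivities through the same
#' delay machinery as the states) and returns `C(t) = p/x * dx/dp`. This is
#' the independent reference the finite-difference [mcc()] is checked
#' against; it is not the default route.
#'
#' @inheritParams mcc
#' @param rtol,atol Integration tolerances.
#' @return `control_coefficients` object.
#' @export
forward_sensitivity_mcc <- function(params, parameter_id,
                                    variable_id = "STAT1Dn", dose = 100,
                                    times = seq(0, 540, by = 10), eps = 1e-9,
                                    rtol = 1e-8, atol = 1e-10) {
  validate_parameters(params)
  if (!variable_id %in% pathway_state_names) {
    stop("forward sensitivities are computed for state variables only")
  }
  pv <- params[[parameter_id]]
  if (pv <= 0) stop("parameter must be > 0")
  y0 <- basal_steady_state(params)
  # initial-condition sensitivity (basal state depends on the parameters)
  h0 <- 1e-6 * pv
  ic <- function(p) {
    q <- params; q[parameter_id] <- p
    as.numeric(basal_steady_state(pathway_parameters(q)))
  }
  s0 <- (ic(pv + h0) - ic(pv - h0)) / (2 * h0)
  basal <- as.numeric(y0)
  idx_Dn <- .STATE_IDX[["STAT1Dn"]]
  f_core <- function(t, y, p, lagDn_socs, lagDn_stat) {
    # lags are held fixed here so the Jacobian pieces separate cleanly
    parms <- list(p = p, dose = dose, basal = basal, feedback = "protein",
                  lag_fun = function(t, tau, idx, channel) {
                    if (channel == "socs") lagDn_socs else lagDn_stat
                  })
    pathway_rhs(t, y, parms)[[1L]]
  }
  taus <- c(params[["tau_socs"]], params[["tau_stat"]])
  rhs <- function(t, z, parms) {
    y <- z[1:8]; s <- z[9:16]
    lag_state <- function(tau, i) {
      if (tau <= 0) z[[i]]
      else if (t <= tau) c(basal, s0)[[i]]
      else deSolve::lagvalue(t - tau, i)
    }
    yl_socs <- lag_state(taus[1], idx_Dn)
    yl_stat <- lag_state(taus[2], idx_Dn)
    sl_socs <- lag_state(taus[1], 8L + idx_Dn)
    sl_stat <- lag_state(taus[2], 8L + idx_Dn)
    f0 <- f_core(t, y, params, yl_socs, yl_stat)
    # J_y s by directional finite difference along s
    ns <- sqrt(sum(s^2))
    Js <- if (ns > 0) {
      h <- 1e-7 * max(1, sqrt(sum(y^2))) / ns
      (f_core(t, y + h * s, params, yl_socs, yl_stat) -
         f_core(t, y - h * s, params, yl_socs, yl_stat)) / (2 * h)
    } else numeric(8)
    # df/dp at fixed state and lags
    hp <- 1e-6 * pv
    pplus <- params; pplus[parameter_id] <- pv + hp
    pminus <- params; pminus[parameter_id] <- pv - hp
    fp <- (f_core(t, y, pplus, yl_socs, yl_stat) -
             f_core(t, y, pminus, yl_socs, yl_stat)) / (2 * hp)
    # delayed-term contribution: lagged STAT1Dn feeds the two mRNA equations
    dlag <- numeric(8)
    dlag[6L] <- params[["k_tc_stat"]] * sl_stat
    dlag[7L] <- params[["k_tc_socs"]] * sl_socs
    # the finite-difference Js above already differentiates with lags held
    # fixed, and fp holds state and lags fixed, so dlag adds the lag channel
    list(c(f0, Js + dlag + fp))
  }
  z0 <- c(basal, s0)
  out <- deSolve::dede(y = z0, times = times, func = rhs, parms = NULL,
                       rtol = rtol, atol = atol)
  i <- .STATE_IDX[[variable_id]]
  x <- out[, 1L + i]
  s <- out[, 1L + 8L + i]
  coef <- ifelse(abs(x) < eps, NA_real_, pv * s / x)
  structure(list(time = times, coefficient = coef,
                 parameter_id = parameter_id, variable_id = variable_id,
                 delta = 0, dose = dose),
            class = "control_coefficients")
}
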