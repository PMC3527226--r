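#' Chi-squared confidence threshold
#'
#' The likelihood threshold defining a confidence interval from a profile:
#' the chi-squared quantile at level `alpha` with `df` degrees of freedom.
#' `df = 1` gives the pointwise CI, `df =` number of free parameters the
#' simultaneous CI; an externally determined effective dof (see
#' [effective_dof()]) may be supplied instead.
#'
#' @param alpha Confidence level in (0, 1).
#' @param df Degrees of freedom, >= 1.
#' @return Positive threshold on the chi-squared difference scale.
#' @examples
#' ci_threshold(0.95, 1) # 3.841
#' @export
ci_threshold <- function(alpha, df) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)")
  if (df < 1) stop("df must be >= 1")
  stats::qchisq(alpha, df = df)
}

#' Profile likelihood of one parameter
#'
#' Walks the parameter in both directions from the best fit with adaptive
#' steps (targeting chi-squared increments of ~0.1 x the largest threshold,
#' clamped per step), re-minimizing all other free parameters at every grid
#' point with a warm start from the neighbouring point (a small cold
#' multistart is attempted before declaring a point failed). A direction
#' stops at the first point beyond the largest threshold, at the step limit,
#' or on persistent numeric failure. If re-minimization finds a cost below
#' the anchor by more than `reanchor_tol`, the optimum is re-anchored and the
#' profile restarted. CI bounds are located by linear interpolation of the
#' chi-squared difference across the crossing; a side that never crosses is
#' reported as the explored endpoint with an `unbounded` flag, never an
#' extrapolated number.
#'
#' @param parameter_id Name of the profiled parameter (must be free in the
#'   fit).
#' @param fit A converged [fit_model()] result.
#' @param data Dataset used for the fit.
#' @param thresholds Named numeric vector of chi-squared thresholds (e.g.
#'   `c(pointwise = ci_threshold(a, 1), simultaneous = ci_threshold(a, k))`).
#' @param max_steps Maximum grid points per direction.
#' @param step_target Targeted chi-squared increment per step, as a fraction
#'   of the largest threshold.
#' @param step_clamp Two-element range clamping the transformed-space step
#'   (decades for log10-scaled parameters).
#' @param reanchor_tol Re-anchoring tolerance on the chi-squared difference.
#' @param max_reanchor Maximum number of re-anchoring restarts.
#' @return Object of class `likelihood_profile`: grid values (natural
#'   scale), `delta_chi2`, co-fitted parameter matrix, per-threshold CI
#'   table, status, termination reasons, and the (possibly re-anchored)
#'   optimum.
#' @export
profile_likelihood <- function(parameter_id, fit, data,
                               thresholds = c(pointwise = ci_threshold(0.95, 1)),
                               max_steps = 100L, step_target = 0.1,
                               step_clamp = c(1e-3, 0.3),
                               reanchor_tol = 1e-3, max_reanchor = 3L) {
  settings <- fit$settings
  if (!parameter_id %in% names(settings$lower)) {
    stop("parameter '", parameter_id, "' is not free in the fit")
  }
  if (is.null(names(thresholds))) {
    names(thresholds) <- paste0("t", seq_along(thresholds))
  }
  thr_max <- max(thresholds)
  theta_hat <- fit$theta_hat
  chi2_hat <- fit$chi2_hat
  model <- fit$model

  others <- setdiff(names(settings$lower), parameter_id)
  sub_settings <- if (length(others) > 0) {
    fit_settings(settings$lower[others], settings$upper[others],
                 log10 = settings$log10[others], restarts = 1L,
                 anneal = list(steps = 0L), local_tol = settings$local_tol,
                 seed = settings$seed, fixed = settings$fixed)
  } else NULL

  is_log <- settings$log10[[parameter_id]]
  tlo <- if (is_log) log10(settings$lower[[parameter_id]]) else settings$lower[[parameter_id]]
  thi <- if (is_log) log10(settings$upper[[parameter_id]]) else settings$upper[[parameter_id]]
  clamp <- if (is_log) step_clamp else step_clamp * (thi - tlo) / 3

  reminimize <- function(pval, warm) {
    fixed <- c(settings$fixed, stats::setNames(pval, parameter_id))
    if (is.null(sub_settings)) {
      cost <- tryCatch(chi_squared(fixed, data, model), error = function(e) Inf)
      return(list(cost = cost, theta = stats::setNames(numeric(0), character(0))))
    }
    ss <- sub_settings
    ss$fixed <- fixed
    obj <- .make_objective(data, ss, model)
    lzs <- .to_transformed(ss$lower, ss); uzs <- .to_transformed(ss$upper, ss)
    zw <- pmin(pmax(.to_transformed(warm[others], ss), lzs), uzs)
    loc <- tryCatch(stats::nlminb(zw, obj, lower = lzs, upper = uzs,
                                  control = list(iter.max = 300, eval.max = 1000)),
                    error = function(e) NULL)
    best <- if (!is.null(loc) && is.finite(loc$objective) && loc$objective < 1e299) {
      list(cost = loc$objective, z = loc$par)
    } else NULL
    if (is.null(best)) {
      # cold multistart fallback
      set.seed(settings$seed + 7L)
      for (k in 1:5) {
        z0 <- lzs + stats::runif(length(lzs)) * (uzs - lzs)
        loc <- tryCatch(stats::nlminb(z0, obj, lower = lzs, upper = uzs,
                                      control = list(iter.max = 300)),
                        error = function(e) NULL)
        if (!is.null(loc) && is.finite(loc$objective) && loc$objective < 1e299 &&
            (is.null(best) || loc$objective < best$cost)) {
          best <- list(cost = loc$objective, z = loc$par)
        }
      }
    }
    if (is.null(best)) return(list(cost = Inf, theta = NULL))
    list(cost = best$cost, theta = .from_transformed(best$z, ss))
  }

  for (attempt in seq_len(max_reanchor + 1L)) {
    p0 <- if (is_log) log10(theta_hat[[parameter_id]]) else theta_hat[[parameter_id]]
    grid <- list(list(t = p0, cost = chi2_hat, theta = theta_hat[others]))
    term <- c(down = "step limit", up = "step limit")
    reanchored <- FALSE

    for (dir in c(-1, 1)) {
      dname <- if (dir < 0) "down" else "up"
      step <- clamp[1] * 10
      tcur <- p0
      warm <- theta_hat
      last_cost <- chi2_hat
      for (s in seq_len(max_steps)) {
        tnew <- tcur + dir * step
        hit_bound <- FALSE
        if (tnew <= tlo) { tnew <- tlo; hit_bound <- TRUE }
        if (tnew >= thi) { tnew <- thi; hit_bound <- TRUE }
        pval <- if (is_log) 10^tnew else tnew
        res <- reminimize(pval, warm)
        if (!is.finite(res$cost)) { term[dname] <- "numeric failure"; break }
        dch <- res$cost - chi2_hat
        # overshoot: the increment of this single step is far above the
        # target -> refine the step instead of recording a coarse crossing
        if (dch > thr_max && step > clamp[1] * 1.0001 &&
            res$cost - last_cost > 4 * step_target * thr_max) {
          step <- max(step / 4, clamp[1])
          next
        }
        if (dch < -reanchor_tol) {
          theta_hat <- c(stats::setNames(pval, parameter_id), res$theta)[names(settings$lower)]
          chi2_hat <- res$cost
          reanchored <- TRUE
          break
        }
        grid[[length(grid) + 1L]] <- list(t = tnew, cost = res$cost,
                                          theta = res$theta[others])
        warm[others] <- res$theta[others]
        if (dch > thr_max) { term[dname] <- "threshold crossed"; break }
        if (hit_bound) { term[dname] <- "bound reached"; break }
        # adapt step toward the target increment
        inc <- max(res$cost - last_cost, 1e-6)
        step <- min(max(step * min(max(step_target * thr_max / inc, 0.5), 2),
                        clamp[1]), clamp[2])
        last_cost <- res$cost
        tcur <- tnew
      }
      if (reanchored) break
    }
    if (!reanchored) {
      ord <- order(vapply(grid, function(g) g$t, 0))
      tgrid <- vapply(grid, function(g) g$t, 0)[ord]
      costs <- vapply(grid, function(g) g$cost, 0)[ord]
      cofit <- do.call(rbind, lapply(grid[ord], function(g) {
        if (length(others) == 0) return(matrix(0, 1, 0))
        matrix(g$theta[others], nrow = 1, dimnames = list(NULL, others))
      }))
      values <- if (is_log) 10^tgrid else tgrid
      delta <- costs - chi2_hat
      ci <- .extract_cis(values, delta, thresholds,
                         opt = theta_hat[[parameter_id]], term = term)
      prof <- structure(list(
        parameter_id = parameter_id, values = values, delta_chi2 = delta,
        cofit = cofit, ci = ci, thresholds = thresholds,
        termination = term, theta_hat = theta_hat, chi2_hat = chi2_hat,
        others = others, settings = settings, log10 = is_log,
        reanchor_tol = reanchor_tol), class = "likelihood_profile")
      prof$status <- classify_profile(prof, thr_max)
      return(prof)
    }
    fit$theta_hat <- theta_hat
    fit$chi2_hat <- chi2_hat
  }
  stop("profile re-anchored more than max_reanchor times for ", parameter_id)
}

.extract_cis <- function(values, delta, thresholds, opt, term) {
  do.call(rbind, lapply(names(thresholds), function(nm) {
    thr <- thresholds[[nm]]
    left <- values <= opt
    lower <- .cross(values[left], delta[left], thr, lower = TRUE)
    right <- values >= opt
    upper <- .cross(values[right], delta[right], thr, lower = FALSE)
    data.frame(threshold_id = nm, threshold = thr,
               lower = lower$value, lower_unbounded = lower$unbounded,
               upper = upper$value, upper_unbounded = upper$unbounded)
  }))
}

# linear interpolation of the outermost crossing of `thr` on one side
.cross <- function(v, d, thr, lower) {
  if (length(v) == 0) return(list(value = NA_real_, unbounded = TRUE))
  if (lower) { v <- rev(v); d <- rev(d) } # walk outward from the optimum
  above <- which(d > thr)
  if (length(above) == 0) {
    return(list(value = v[length(v)], unbounded = TRUE))
  }
  i <- above[1]
  if (i == 1) return(list(value = v[1], unbounded = FALSE))
  f <- (thr - d[i - 1]) / (d[i] - d[i - 1])
  list(value = v[i - 1] + f * (v[i] - v[i - 1]), unbounded = FALSE)
}

#' Classify a profile as identifiable / practically / structurally
#' nonidentifiable
#'
#' Identifiable: both CI bounds at `threshold` finite. Structurally
#' nonidentifiable: the profile stays below `flatness_frac * threshold` over
#' the whole explored range in both directions (a flat profile from a
#' redundant parameterization). Practically nonidentifiable otherwise: the
#' profile rises but the CI is infinite in at least one direction. A side
#' terminated by numeric failure yields `"indeterminate"`.
#'
#' @param profile `likelihood_profile`.
#' @param threshold Chi-squared threshold to classify against (default: the
#'   largest one stored in the profile).
#' @param flatness_frac Flatness tolerance as a fraction of `threshold`.
#' @return One of `"identifiable"`, `"practically_nonidentifiable"`,
#'   `"structurally_nonidentifiable"`, `"indeterminate"`.
#' @export
classify_profile <- function(profile, threshold = max(profile$thresholds),
                             flatness_frac = 0.01) {
  if (any(profile$termination == "numeric failure")) return("indeterminate")
  opt <- profile$theta_hat[[profile$parameter_id]]
  left <- profile$values <= opt
  lo <- .cross(profile$values[left], profile$delta_chi2[left], threshold, TRUE)
  right <- profile$values >= opt
  hi <- .cross(profile$values[right], profile$delta_chi2[right], threshold, FALSE)
  if (!lo$unbounded && !hi$unbounded) return("identifiable")
  if (max(profile$delta_chi2) < flatness_frac * threshold) {
    return("structurally_nonidentifiable")
  }
  "practically_nonidentifiable"
}

#' @export
print.likelihood_profile <- function(x, ...) {
  cat("<likelihood_profile>", x$parameter_id, "-", x$status, "\n",
      length(x$values), "grid points; termination:",
      paste(names(x$termination), x$termination, sep = "=", collapse = ", "),
      "\n")
  print(x$ci)
  invisible(x)
}

#' Log-log relation between the profiled and a co-fitted parameter
#'
#' Least-squares line through (log10 profiled value, log10 co-fitted value)
#' over the in-CI grid points. A slope of -1 with low residual indicates
#' inverse proportionality (constant product) — the signature of two
#' parameters acting only through their product.
#'
#' @param profile `likelihood_profile`.
#' @param cofit_parameter_id Co-fitted parameter to relate.
#' @param threshold Chi-squared threshold delimiting the in-CI points
#'   (default: largest stored).
#' @return List: `slope`, `intercept`, `residual_sd`, `n`, `unreliable`
#'   (TRUE when the co-fitted parameter sits on a bound for more than half
#'   of the grid points).
#' @export
profile_correlation <- function(profile, cofit_parameter_id,
                                threshold = max(profile$thresholds)) {
  if (!cofit_parameter_id %in% colnames(profile$cofit)) {
    stop("'", cofit_parameter_id, "' was not co-fitted in this profile")
  }
  inci <- profile$delta_chi2 <= threshold
  if (sum(inci) < 5) stop("need >= 5 in-CI grid points, got ", sum(inci))
  x <- profile$values[inci]
  y <- profile$cofit[inci, cofit_parameter_id]
  lo <- profile$settings$lower[[cofit_parameter_id]]
  hi <- profile$settings$upper[[cofit_parameter_id]]
  at_bound <- mean(y <= lo * (1 + 1e-6) | y >= hi * (1 - 1e-6))
  fit <- stats::lm(log10(y) ~ log10(x))
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       residual_sd = stats::sd(stats::residuals(fit)),
       n = sum(inci),
       unreliable = at_bound > 0.5)
}

#' Trajectory uncertainty band over a profile's confidence interval
#'
#' Selects `n_sets` parameter vectors (profiled value plus its co-fitted
#' partners, remaining parameters at the best fit) evenly spaced along the
#' in-CI portion of the profile, simulates each, and returns the per-time
#' envelope. The best-fit trajectory is always a member.
#'
#' @param profile `likelihood_profile`.
#' @param base Full `pathway_parameters` vector for parameters outside the
#'   fit.
#' @param what State variable or observable name.
#' @param dose Dose, ng/ml.
#' @param times Time grid, min.
#' @param n_sets Number of parameter sets along the profile (default 11).
#' @param threshold Chi-squared threshold delimiting the in-CI portion.
#' @param sim_args Extra arguments for [simulate_pathway()].
#' @return Object of class `trajectory_band`: `time`, `members` (matrix, one
#'   column per set; column "best" is the best fit), `lower`, `upper`,
#'   `member_values` (profiled parameter value per member).
#' @export
trajectory_band <- function(profile, base, what = "STAT1Dn", dose = 100,
                            times = seq(0, 540, by = 5), n_sets = 11L,
                            threshold = max(profile$thresholds),
                            sim_args = list()) {
  if (n_sets < 1) stop("n_sets must be >= 1")
  inci <- which(profile$delta_chi2 <= threshold)
  if (length(inci) == 0) stop("no grid points inside the confidence interval")
  # n_sets = 1 degenerates to the best fit alone (zero-width band)
  pick <- if (n_sets == 1) integer(0) else {
    inci[unique(round(seq(1, length(inci),
                          length.out = min(n_sets - 1, length(inci)))))]
  }
  sim_one <- function(theta) {
    p <- pathway_parameters(replace(base, names(theta), theta))
    traj <- do.call(simulate_pathway,
                    c(list(params = p, dose = dose, times = times), sim_args))
    if (what %in% pathway_state_names) traj$states[, what] else observe(traj, p)[[what]]
  }
  members <- vapply(pick, function(i) {
    theta <- profile$theta_hat
    theta[profile$parameter_id] <- profile$values[i]
    if (ncol(profile$cofit) > 0) theta[colnames(profile$cofit)] <- profile$cofit[i, ]
    sim_one(theta)
  }, numeric(length(times)))
  members <- cbind(matrix(members, nrow = length(times)),
                   sim_one(profile$theta_hat))
  colnames(members) <- c(if (length(pick) > 0) paste0("set", seq_along(pick)),
                         "best")
  structure(list(time = times, members = members,
                 lower = apply(members, 1, min), upper = apply(members, 1, max),
                 member_values = c(profile$values[pick],
                                   profile$theta_hat[[profile$parameter_id]]),
                 what = what, dose = dose,
                 parameter_id = profile$parameter_id),
            class = "trajectory_band")
}

#' Write a trajectory band as tidy CSV (time_min, variable, member_index,
#' value)
#' @param band `trajectory_band`.
#' @param path Output path.
#' @export
write_band <- function(band, path) {
  tidy <- do.call(rbind, lapply(seq_len(ncol(band$members)), function(j) {
    data.frame(time_min = band$time, variable = band$what, member_index = j,
               value = band$members[, j])
  }))
  utils::write.csv(tidy, path, row.names = FALSE)
  invisible(path)
}

#' Serialize likelihood profiles to JSON
#' @param profiles A `likelihood_profile` or list of them.
#' @param path Output path.
#' @export
write_profiles <- function(profiles, path) {
  if (inherits(profiles, "likelihood_profile")) profiles <- list(profiles)
  out <- lapply(profiles, function(pr) {
    list(parameter_id = pr$parameter_id, values = pr$values,
         delta_chi2 = pr$delta_chi2,
         cofit = as.data.frame(pr$cofit), ci = pr$ci, status = pr$status,
         termination = as.list(pr$termination), chi2_hat = pr$chi2_hat,
         theta_hat = as.list(pr$theta_hat))
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
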