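#' Prediction-model interface
#'
#' The estimation, identifiability and overfitting machinery is generic over
#' a "prediction model": an object whose `predict(theta, data)` returns the
#' model observable for every dataset record, given a named parameter vector
#' `theta`. This keeps the pathway model pluggable and lets closed-form
#' models (lines, products) serve as analytic references.
#'
#' @param predict Function `(theta, data) -> numeric` aligned with the rows
#'   of `data`.
#' @param name Label.
#' @return Object of class `prediction_model`.
#' @export
prediction_model <- function(predict, name = "model") {
  stopifnot(is.function(predict))
  structure(list(predict = predict, name = name), class = "prediction_model")
}

#' Pathway model as a prediction model
#'
#' Wraps [simulate_pathway()] + [observe()]: free parameters in `theta`
#' override `base`; the model is simulated once per dose at the union of the
#' record times and the records are matched by (dose, observable, time).
#'
#' @param base Full `pathway_parameters` vector supplying every parameter
#'   not present in `theta`.
#' @param sim_args List of extra arguments for [simulate_pathway()].
#' @return A `prediction_model`.
#' @export
pathway_prediction_model <- function(base, sim_args = list()) {
  base <- pathway_parameters(base)
  predict <- function(theta, data) {
    p <- base
    if (length(theta) > 0) {
      unknown <- setdiff(names(theta), pathway_parameter_names)
      if (length(unknown) > 0) {
        stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
      }
      p[names(theta)] <- theta
    }
    p <- pathway_parameters(p)
    out <- numeric(nrow(data))
    for (dose in unique(data$dose_ng_ml)) {
      i <- which(data$dose_ng_ml == dose)
      grid <- sort(unique(c(0, data$time_min[i])))
      traj <- do.call(simulate_pathway,
                      c(list(params = p, dose = dose, times = grid), sim_args))
      obs <- observe(traj, p)
      out[i] <- mapply(function(tm, ob) obs[[ob]][match(tm, obs$time_min)],
                       data$time_min[i], data$observable[i])
    }
    out
  }
  prediction_model(predict, name = "stat1_pathway")
}

#' Chi-squared cost of a parameter set against a dataset
#'
#' The double sum over observables and time points of squared,
#' sigma-normalized residuals between the data values and the model
#' observables evaluated at the record times and doses — the maximum
#' likelihood cost under Gaussian measurement noise.
#'
#' @param params Named parameter vector (free parameters for `model`, or a
#'   full `pathway_parameters` vector, in which case `model` defaults to the
#'   pathway model built on it).
#' @param data Dataset.
#' @param model A `prediction_model`.
#' @return Non-negative number.
#' @export
chi_squared <- function(params, data,
                        model = pathway_prediction_model(params)) {
  validate_dataset(data)
  pred <- model$predict(params, data)
  if (length(pred) != nrow(data)) {
    stop("model returned ", length(pred), " predictions for ", nrow(data),
         " records")
  }
  bad <- which(!is.finite(pred))
  if (length(bad) > 0) {
    stop("model observable undefined at data record(s) ",
         paste(utils::head(bad, 10), collapse = ", "),
         " (", paste(unique(data$observable[bad]), collapse = ", "), ")")
  }
  sum(((data$value - pred) / data$sigma)^2)
}

#' Settings for multistart hybrid fitting
#'
#' @param lower,upper Named positive bounds for every free parameter.
#' @param log10 Named logical: optimize this parameter in log10 space.
#'   Default: `TRUE` for everything except delays (names starting `tau_`),
#'   which are walked linearly.
#' @param restarts Number of multistart repetitions (study default 50).
#' @param anneal List: `steps` (Metropolis steps per restart), `t0` (initial
#'   temperature; `NULL` scales it to the start cost), `cooling` (geometric
#'   factor), `step_frac` (proposal SD as a fraction of each transformed
#'   bound range).
#' @param local_tol List: `cost` and `par` tolerances of the local
#'   quasi-Newton refinement.
#' @param seed Integer seed; every restart derives its own stream from it.
#' @param fixed Named numeric vector of parameters held fixed (merged into
#'   the model but never optimized).
#' @return Object of class `fit_settings`.
#' @export
fit_settings <- function(lower, upper, log10 = NULL, restarts = 50L,
                         anneal = list(), local_tol = list(), seed = 1L,
                         fixed = NULL) {
  stopifnot(length(lower) == length(upper),
            !is.null(names(lower)), all(names(lower) == names(upper)))
  if (any(!is.finite(lower)) || any(!is.finite(upper)) ||
      any(lower >= upper)) {
    stop("bounds must be finite with lower < upper")
  }
  if (restarts < 1) stop("restarts must be >= 1")
  if (is.null(log10)) {
    log10 <- !startsWith(names(lower), "tau_")
    names(log10) <- names(lower)
  }
  if (any(log10 & lower <= 0)) {
    stop("log10-scaled parameters need positive lower bounds: ",
         paste(names(lower)[log10 & lower <= 0], collapse = ", "))
  }
  anneal <- utils::modifyList(
    list(steps = 200L, t0 = NULL, cooling = 0.97, step_frac = 0.08), anneal)
  local_tol <- utils::modifyList(list(cost = 1e-10, par = 1e-8), local_tol)
  structure(list(lower = lower, upper = upper, log10 = log10[names(lower)],
                 restarts = as.integer(restarts), anneal = anneal,
                 local_tol = local_tol, seed = as.integer(seed),
                 fixed = fixed),
            class = "fit_settings")
}

.to_transformed <- function(theta, settings) {
  ifelse(settings$log10, log10(theta), theta)
}
.from_transformed <- function(z, settings) {
  out <- ifelse(settings$log10, 10^z, z)
  names(out) <- names(settings$lower)
  out
}

.make_objective <- function(data, settings, model) {
  fixed <- settings$fixed
  function(z) {
    theta <- .from_transformed(z, settings)
    full <- c(theta, fixed)
    val <- tryCatch(chi_squared(full, data, model), error = function(e) NA)
    # failed integrations get a large finite cost so the search continues
    if (!is.finite(val)) 1e300 else val
  }
}

#' Hybrid multistart fit
#'
#' For each restart a start point is drawn uniformly in the transformed
#' (log10-bounded) box, a simulated-annealing stage (Metropolis acceptance on
#' the chi-squared cost, geometric cooling, bound-reflected Gaussian
#' proposals) performs the global search, and a deterministic quasi-Newton
#' stage ([stats::nlminb()], a trust-region-type local search) refines it.
#' The best result across restarts is reported; ties within 1e-9 go to the
#' earliest restart. Failed integrations during the search contribute a
#' large finite cost rather than aborting the restart.
#'
#' @param data Dataset.
#' @param settings [fit_settings()].
#' @param model A `prediction_model`.
#' @param start Optional named start vector; when given, restart 1 starts
#'   there instead of at a random draw.
#' @return Object of class `fit_result`: `theta_hat`, `chi2_hat`, `restarts`
#'   (data frame of per-restart provenance), `settings`, `seed`, `model`.
#' @export
fit_model <- function(data, settings, model, start = NULL) {
  validate_dataset(data)
  obj <- .make_objective(data, settings, model)
  lz <- .to_transformed(settings$lower, settings)
  uz <- .to_transformed(settings$upper, settings)
  npar <- length(lz)
  set.seed(settings$seed)
  restart_seeds <- sample.int(.Machine$integer.max - 1L, settings$restarts)

  rows <- vector("list", settings$restarts)
  best <- NULL
  for (i in seq_len(settings$restarts)) {
    set.seed(restart_seeds[i])
    z0 <- if (i == 1L && !is.null(start)) {
      .to_transformed(start[names(settings$lower)], settings)
    } else {
      lz + stats::runif(npar) * (uz - lz)
    }
    cost0 <- obj(z0)
    z1 <- .anneal_stage(obj, z0, cost0, lz, uz, settings$anneal)
    loc <- stats::nlminb(
      z1$z, obj, lower = lz, upper = uz,
      control = list(abs.tol = settings$local_tol$cost,
                     x.tol = settings$local_tol$par, iter.max = 500,
                     eval.max = 2000))
    end_cost <- min(loc$objective, z1$cost, cost0)
    end_z <- if (loc$objective <= min(z1$cost, cost0)) loc$par
             else if (z1$cost <= cost0) z1$z else z0
    converged <- is.finite(loc$objective) && loc$convergence %in% c(0L, 1L) &&
      end_cost < 1e299
    rows[[i]] <- data.frame(restart = i, start_cost = cost0,
                            anneal_cost = z1$cost, end_cost = end_cost,
                            converged = converged)
    if (converged && (is.null(best) || end_cost < best$cost - 1e-9)) {
      best <- list(cost = end_cost, z = end_z, restart = i)
    }
  }
  restarts <- do.call(rbind, rows)
  if (is.null(best)) {
    stop("fit failed: no restart converged to a finite cost (",
         settings$restarts, " restarts; min start cost ",
         format(min(restarts$start_cost)), ")")
  }
  theta_hat <- .from_transformed(best$z, settings)
  structure(list(theta_hat = theta_hat, chi2_hat = best$cost,
                 restarts = restarts, best_restart = best$restart,
                 settings = settings, seed = settings$seed, model = model),
            class = "fit_result")
}

.anneal_stage <- function(obj, z0, cost0, lz, uz, anneal) {
  z <- z0; cost <- cost0
  zbest <- z0; cbest <- cost0
  if (anneal$steps < 1) return(list(z = zbest, cost = cbest))
  temp <- if (is.null(anneal$t0)) max(abs(cost0), 1) / 3 else anneal$t0
  sdv <- anneal$step_frac * (uz - lz)
  for (s in seq_len(anneal$steps)) {
    zp <- z + stats::rnorm(length(z), 0, sdv)
    # reflect into bounds
    zp <- pmin(pmax(zp, 2 * lz - zp), uz)
    zp <- pmin(pmax(zp, lz), uz)
    cp <- obj(zp)
    if (cp <= cost || stats::runif(1) < exp((cost - cp) / temp)) {
      z <- zp; cost <- cp
      if (cost < cbest) { zbest <- z; cbest <- cost }
    }
    temp <- temp * anneal$cooling
  }
  list(z = zbest, cost = cbest)
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> chi2 =", format(x$chi2_hat), "at restart",
      x$best_restart, "of", nrow(x$restarts), "\n")
  print(x$theta_hat)
  invisible(x)
}

#' Serialize a fit result (with restart provenance) to JSON
#'
#' @param fit `fit_result`.
#' @param path Output path.
#' @export
write_fit_result <- function(fit, path) {
  out <- list(theta_hat = as.list(fit$theta_hat), chi2_hat = fit$chi2_hat,
              best_restart = fit$best_restart, seed = fit$seed,
              restarts = fit$restarts,
              settings = list(lower = as.list(fit$settings$lower),
                              upper = as.list(fit$settings$upper),
                              restarts = fit$settings$restarts,
                              anneal = fit$settings$anneal))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
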