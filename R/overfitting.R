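#' Overfitting statistics from randomized datasets
#'
#' For each of `n_random` randomized datasets (per-record parametric
#' bootstrap, see [randomize_like()]): refit the model to the randomized
#' data, evaluate the chi-squared of the refitted parameter vector against
#' the ORIGINAL data, and record the difference to the original best-fit
#' chi-squared. The distribution of this statistic is compared to
#' chi-squared laws to diagnose how many degrees of freedom the model
#' effectively spends on noise.
#'
#' @param data Original dataset.
#' @param fit Converged [fit_model()] result on `data`.
#' @param settings Fit settings for the random refits (typically the main
#'   settings with fewer restarts).
#' @param n_random Number of randomized datasets.
#' @param seed Integer seed; each randomization derives a sub-seed.
#' @param randomize_method Passed to [randomize_like()].
#' @return Object of class `overfit_distribution`: `samples` (NA for failed
#'   refits), `n_random`, `n_missing`, `failures`, `seed`.
#' @export
overfit_samples <- function(data, fit, settings = fit$settings,
                            n_random = 400L, seed = 1L,
                            randomize_method = "parametric") {
  if (n_random < 1) stop("n_random must be >= 1")
  set.seed(as.integer(seed))
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_random)
  samples <- rep(NA_real_, n_random)
  failures <- character(0)
  for (j in seq_len(n_random)) {
    rdata <- randomize_like(data, seed = sub_seeds[j], method = randomize_method)
    ss <- settings
    ss$seed <- sub_seeds[j]
    refit <- tryCatch(
      fit_model(rdata, ss, fit$model, start = fit$theta_hat),
      error = function(e) e)
    if (inherits(refit, "error")) {
      failures <- c(failures, sprintf("sample %d: %s", j, conditionMessage(refit)))
      next
    }
    chi2_orig <- chi_squared(c(refit$theta_hat, settings$fixed), data, fit$model)
    samples[j] <- chi2_orig - fit$chi2_hat
  }
  n_missing <- sum(is.na(samples))
  if (n_missing > 0) {
    message("overfit_samples: ", n_missing, "/", n_random, " refits failed")
  }
  structure(list(samples = samples, n_random = n_random,
                 n_missing = n_missing, failures = failures, seed = seed),
            class = "overfit_distribution")
}

#' @export
print.overfit_distribution <- function(x, ...) {
  ok <- x$samples[!is.na(x$samples)]
  cat("<overfit_distribution>", length(ok), "samples (", x$n_missing,
      "missing ), mean =", format(mean(ok)), "\n")
  invisible(x)
}

# Kolmogorov-Smirnov distance between samples and the chi-squared CDF
.ks_chisq <- function(samples, df) {
  x <- sort(samples)
  n <- length(x)
  f <- stats::pchisq(x, df = df)
  max(pmax(abs(seq_len(n) / n - f), abs((seq_len(n) - 1) / n - f)))
}

#' Effective degrees of freedom of the overfitting distribution
#'
#' For each candidate dof computes the Kolmogorov-Smirnov distance between
#' the empirical CDF of the overfitting samples and the chi-squared CDF with
#' that dof, and selects the candidate with minimal distance (ties go to the
#' smaller dof). When the samples are essentially all zero (a model with
#' nothing to overfit) the selection degenerates to the smallest candidate
#' and is flagged.
#'
#' @param dist [overfit_samples()] result, or a numeric vector of samples.
#' @param dof_candidates Integer candidates (default 1..20).
#' @param min_samples Minimum number of non-missing samples required.
#' @return List: `dof` (selected), `distance` (named per-candidate KS
#'   distance), `degenerate`.
#' @export
effective_dof <- function(dist, dof_candidates = 1:20, min_samples = 100L) {
  samples <- if (inherits(dist, "overfit_distribution")) dist$samples else dist
  samples <- samples[!is.na(samples)]
  if (length(dof_candidates) == 0) stop("empty dof candidate range")
  if (length(samples) < min_samples) {
    stop("need >= ", min_samples, " non-missing samples, got ", length(samples))
  }
  samples <- pmax(samples, 0) # re-anchoring tolerance can leave tiny negatives
  dof_candidates <- sort(as.integer(dof_candidates))
  d <- vapply(dof_candidates, function(k) .ks_chisq(samples, k), 0)
  names(d) <- dof_candidates
  list(dof = dof_candidates[which.min(d)], distance = d,
       degenerate = max(samples) < 1e-6)
}

#' Confidence level realized by a chi-squared threshold at a given dof
#'
#' The chi-squared CDF at `threshold` with `dof` degrees of freedom: the
#' confidence level that a CI cut at `threshold` actually attains once the
#' effective dof is known. Reducing the dof at a fixed threshold raises the
#' level — the mechanism by which an overfitting analysis upgrades nominal
#' confidence levels.
#'
#' @param threshold Positive chi-squared threshold.
#' @param dof Degrees of freedom, >= 1.
#' @return Level in (0, 1).
#' @examples
#' confidence_level(ci_threshold(0.9, 7), 7) # 0.9
#' @export
confidence_level <- function(threshold, dof) {
  if (threshold <= 0) stop("threshold must be > 0")
  if (dof < 1) stop("dof must be >= 1")
  stats::pchisq(threshold, df = dof)
}
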