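#' Sampling design for synthetic time series
#'
#' Describes which observables are sampled at which times, at which dose(s),
#' with how many replicates, and how per-point measurement errors are
#' assigned. The default design emulates sparse immunoblot /
#' immunofluorescence sampling: 8-12 points per observable over 0-540 min,
#' denser before 120 min, a single 100 ng/ml dose, and sigmas set to 10% of
#' each observable's noise-free series maximum with a floor of 5% of that
#' maximum.
#'
#' @param times Named list mapping observable id to its sampling times (min),
#'   or a single numeric vector used for all observables.
#' @param observables Observable ids included (default all five).
#' @param doses Dose list, ng/ml.
#' @param sigma Either a single positive number (absolute sigma for every
#'   record), a named list per observable, or `NULL` to use the
#'   fraction-of-maximum rule.
#' @param sigma_fraction,sigma_floor_fraction Fraction-of-series-maximum
#'   noise rule used when `sigma` is `NULL`.
#' @param replicates Number of replicate records per (time, observable, dose).
#' @return Object of class `sampling_design`.
#' @export
sampling_design <- function(times = NULL,
                            observables = observable_names,
                            doses = 100,
                            sigma = NULL,
                            sigma_fraction = 0.1,
                            sigma_floor_fraction = 0.05,
                            replicates = 1L) {
  bad <- setdiff(observables, observable_names)
  if (length(bad) > 0) stop("unknown observable(s): ", paste(bad, collapse = ", "))
  default_times <- c(0, 15, 30, 45, 60, 90, 120, 180, 240, 360, 480, 540)
  if (is.null(times)) {
    times <- stats::setNames(rep(list(default_times), length(observables)),
                             observables)
    # the phospho N/C ratio is undefined before stimulation (empty pools)
    if ("ratio_STAT1D_nc" %in% observables) {
      times[["ratio_STAT1D_nc"]] <- setdiff(default_times, 0)
    }
  }
  if (is.numeric(times)) {
    times <- stats::setNames(rep(list(times), length(observables)), observables)
  }
  if (!all(observables %in% names(times))) {
    stop("sampling times missing for: ",
         paste(setdiff(observables, names(times)), collapse = ", "))
  }
  for (ob in observables) {
    tv <- times[[ob]]
    if (length(tv) < 2 || any(tv < 0)) {
      stop("need >= 2 non-negative sampling times per observable (", ob, ")")
    }
  }
  if (!is.null(sigma)) {
    sv <- unlist(sigma)
    if (any(!is.finite(sv)) || any(sv <= 0)) stop("sigmas must be positive")
  }
  structure(list(times = times[observables], observables = observables,
                 doses = doses, sigma = sigma,
                 sigma_fraction = sigma_fraction,
                 sigma_floor_fraction = sigma_floor_fraction,
                 replicates = as.integer(replicates)),
            class = "sampling_design")
}

#' Validate a time-series dataset
#'
#' A dataset is a data frame with columns `time_min`, `observable`, `value`,
#' `sigma`, `dose_ng_ml`, `replicate` — one record per measured point with
#' its Gaussian measurement error.
#'
#' @param data Data frame.
#' @return `data`, invisibly; errors on violation.
#' @export
validate_dataset <- function(data) {
  req <- c("time_min", "observable", "value", "sigma", "dose_ng_ml")
  miss <- setdiff(req, names(data))
  if (length(miss) > 0) stop("dataset missing column(s): ",
                             paste(miss, collapse = ", "))
  if (nrow(data) == 0) stop("dataset is empty")
  bad <- which(!(data$observable %in% observable_names))
  if (length(bad) > 0) {
    stop("unknown observable id(s) in row(s) ", paste(bad, collapse = ", "),
         ": ", paste(unique(data$observable[bad]), collapse = ", "))
  }
  bad <- which(!is.finite(data$sigma) | data$sigma <= 0)
  if (length(bad) > 0) {
    stop("sigma must be > 0; violated in row(s) ", paste(bad, collapse = ", "))
  }
  bad <- which(data$time_min < 0)
  if (length(bad) > 0) {
    stop("negative time in row(s) ", paste(bad, collapse = ", "))
  }
  invisible(data)
}

#' Counts entering the chi-squared double sum
#'
#' @param data Dataset.
#' @return List with `n_records` (total terms), `n_observables` and per
#'   observable the number of time points.
#' @export
dataset_counts <- function(data) {
  validate_dataset(data)
  per <- table(data$observable)
  list(n_records = nrow(data),
       n_observables = length(per),
       n_timepoints = as.list(per))
}

#' Generate a synthetic dataset from the pathway model
#'
#' Simulates the model per dose, evaluates the design's observables at the
#' design times and adds independent Gaussian noise with the record's sigma
#' (the measurement-noise assumption of the chi-squared cost). Values are
#' left untruncated, so records may be negative. Identical seeds give
#' identical datasets.
#'
#' @param params Generating parameter set.
#' @param design [sampling_design()].
#' @param seed Integer seed.
#' @param ... Passed to [simulate_pathway()].
#' @return Dataset data frame (see [validate_dataset()]) with attributes
#'   `cell_type`, `seed` and `params`.
#' @export
generate_dataset <- function(params, design = sampling_design(), seed = 1L,
                             ...) {
  validate_parameters(params)
  recs <- list()
  for (dose in design$doses) {
    grid <- sort(unique(c(0, unlist(design$times))))
    traj <- simulate_pathway(params, dose = dose, times = grid, ...)
    obs <- observe(traj, params)
    for (ob in design$observables) {
      tv <- design$times[[ob]]
      truth <- obs[[ob]][match(tv, obs$time_min)]
      if (anyNA(truth)) {
        stop("observable ", ob, " is undefined at design time(s) ",
             paste(tv[is.na(truth)], collapse = ", "))
      }
      sig <- .resolve_sigma(design, ob, obs[[ob]])
      sig <- rep_len(if (length(sig) == length(obs[[ob]])) {
        sig[match(tv, obs$time_min)]
      } else sig, length(tv))
      for (r in seq_len(design$replicates)) {
        recs[[length(recs) + 1L]] <- data.frame(
          time_min = tv, observable = ob, value = truth, sigma = sig,
          dose_ng_ml = dose, replicate = r)
      }
    }
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  set.seed(as.integer(seed))
  out$value <- out$value + stats::rnorm(nrow(out), 0, out$sigma)
  attr(out, "cell_type") <- attr(params, "cell_type")
  attr(out, "seed") <- as.integer(seed)
  attr(out, "params") <- params
  validate_dataset(out)
  out
}

.resolve_sigma <- function(design, ob, series) {
  if (!is.null(design$sigma)) {
    s <- design$sigma
    if (is.list(s)) {
      if (is.null(s[[ob]])) stop("no sigma for observable ", ob)
      return(s[[ob]])
    }
    return(s)
  }
  mx <- max(abs(series), na.rm = TRUE)
  if (!is.finite(mx) || mx == 0) mx <- 1
  max(design$sigma_fraction * mx, design$sigma_floor_fraction * mx)
}

#' Randomize a dataset for the overfitting analysis
#'
#' Default (`"parametric"`): each record's value is redrawn from a Gaussian
#' centred on the original value with the record's own sigma — the
#' parametric-bootstrap construction under which the overfitting statistic
#' follows its theoretical chi-squared law for linear models. The
#' experimental `"series_moments"` variant instead draws each series i.i.d.
#' from a Gaussian with that observable series' empirical mean and SD.
#' Times, sigmas, observables and doses are preserved.
#'
#' @param data Dataset.
#' @param seed Integer seed.
#' @param method `"parametric"` (default) or `"series_moments"`.
#' @return Dataset of the same shape with randomized values.
#' @export
randomize_like <- function(data, seed = 1L,
                           method = c("parametric", "series_moments")) {
  method <- match.arg(method)
  validate_dataset(data)
  out <- data
  set.seed(as.integer(seed))
  if (method == "parametric") {
    out$value <- data$value + stats::rnorm(nrow(data), 0, data$sigma)
  } else {
    for (ob in unique(data$observable)) {
      i <- which(data$observable == ob)
      m <- mean(data$value[i]); s <- stats::sd(data$value[i])
      if (!is.finite(s) || s == 0) s <- 0
      out$value[i] <- stats::rnorm(length(i), m, s)
    }
  }
  out
}

#' Read / write datasets as tidy CSV
#'
#' Header `time_min, observable, value, sigma, dose_ng_ml, replicate`;
#' UTF-8, "." decimal separator. Values are serialized at full double
#' precision so that `read_dataset(write_dataset(x))` reproduces `x`
#' exactly. Extra unknown columns are preserved and reattached as the
#' `"extra_columns"` attribute on load. Malformed rows are reported with
#' their row numbers.
#'
#' @param data Dataset.
#' @param path File path.
#' @return `read_dataset` returns the dataset data frame.
#' @export
write_dataset <- function(data, path) {
  validate_dataset(data)
  out <- data
  for (col in c("time_min", "value", "sigma", "dose_ng_ml")) {
    out[[col]] <- sprintf("%.17g", out[[col]])
  }
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  req <- c("time_min", "observable", "value", "sigma", "dose_ng_ml")
  miss <- setdiff(req, names(raw))
  if (length(miss) > 0) stop("dataset file missing column(s): ",
                             paste(miss, collapse = ", "))
  for (col in c("time_min", "value", "sigma", "dose_ng_ml")) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]))
    if (length(bad) > 0) {
      stop("malformed numeric value in column '", col, "', row(s) ",
           paste(bad, collapse = ", "))
    }
    raw[[col]] <- v
  }
  if (is.null(raw$replicate)) raw$replicate <- 1L
  extra <- setdiff(names(raw), c(req, "replicate"))
  data <- raw[, c(req, "replicate")]
  if (length(extra) > 0) {
    attr(data, "extra_columns") <- raw[, extra, drop = FALSE]
  }
  validate_dataset(data)
  data
}
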