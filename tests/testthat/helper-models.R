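# Closed-form prediction models and small fixtures shared across tests.

# y(t) = a * t : one-parameter linear-Gaussian model with analytic
# least-squares solution and standard error.
line_model <- function() {
  prediction_model(function(theta, data) theta[["a"]] * data$time_min,
                   name = "line")
}

# y(t) = a + b * t
line2_model <- function() {
  prediction_model(function(theta, data) {
    theta[["a"]] + theta[["b"]] * data$time_min
  }, name = "line2")
}

# y(t) = a + b * t + c * t^2
poly3_model <- function() {
  prediction_model(function(theta, data) {
    theta[["a"]] + theta[["b"]] * data$time_min +
      theta[["c"]] * data$time_min^2
  }, name = "poly3")
}

# observable depends only on the product p1 * p2: structurally
# nonidentifiable pair with exact log-log slope -1 along the profile
product_model <- function() {
  prediction_model(function(theta, data) {
    theta[["p1"]] * theta[["p2"]] * data$time_min
  }, name = "product")
}

# two parameters acting on disjoint observables
disjoint_model <- function() {
  prediction_model(function(theta, data) {
    ifelse(data$observable == "pSTAT1_wb",
           theta[["q1"]] * data$time_min,
           theta[["q2"]] * data$time_min)
  }, name = "disjoint")
}

# dataset construction without the pathway model
make_data <- function(times, values, sigma, observable = "pSTAT1_wb",
                      dose = 100) {
  data.frame(time_min = times, observable = observable, value = values,
             sigma = sigma, dose_ng_ml = dose, replicate = 1L)
}

# line-model dataset with Gaussian noise and its closed-form LS solution
line_fixture <- function(a_true = 2, times = c(10, 20, 30, 40, 50),
                         sigma = 1, seed = 1) {
  set.seed(seed)
  d <- make_data(times, a_true * times + rnorm(length(times), 0, sigma), sigma)
  a_hat <- sum(d$value * d$time_min) / sum(d$time_min^2)
  se <- sigma / sqrt(sum(d$time_min^2))
  list(data = d, a_hat = a_hat, se = se)
}

line_settings <- function(restarts = 1L, seed = 1L) {
  fit_settings(lower = c(a = 1e-3), upper = c(a = 1e3),
               restarts = restarts, anneal = list(steps = 0L), seed = seed)
}

# independent KS distance between samples and a chi-squared law
.ks_dist_for_test <- function(samples, df) {
  x <- sort(pmax(samples, 0))
  n <- length(x)
  f <- pchisq(x, df = df)
  max(pmax(abs(seq_len(n) / n - f), abs((seq_len(n) - 1) / n - f)))
}

# small free-parameter pathway settings used by pathway fitting tests
pathway_settings <- function(free, psc, restarts = 2L, anneal_steps = 25L,
                             seed = 1L) {
  lower <- psc[free] / 30
  upper <- psc[free] * 30
  fit_settings(lower = lower, upper = upper, restarts = restarts,
               anneal = list(steps = anneal_steps), seed = seed,
               fixed = psc[setdiff(pathway_parameter_names, free)])
}
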