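# Independent oracles, written before and kept independent of the package
# implementations they check.

# Brute-force Cox log-partial-likelihood by direct risk-set enumeration
# (valid for untied data, where Efron and Breslow coincide).
logpl_oracle <- function(time, event, x, beta) {
  x <- as.matrix(x)
  eta <- drop(x %*% beta)
  total <- 0
  for (i in which(event == 1)) {
    risk <- which(time >= time[i])
    total <- total + eta[i] - log(sum(exp(eta[risk])))
  }
  total
}

# Empirical survival function (no censoring): fraction strictly surviving t.
empirical_surv <- function(times, t) mean(times > t)

# Eq. 1 oracle value for the cohort-mean volumes (31,400 / 79,900 mm^3),
# computed independently with mpmath to 30 digits before the build and
# frozen here.
RHO_D_ORACLE <- 0.729716549945137

# random small untied survival dataset for oracle sweeps
random_tiny_surv <- function(n_max = 8, p = 1) {
  n <- sample(3:n_max, 1)
  list(
    time = round(stats::rexp(n), 6) + seq_len(n) * 1e-4,  # break ties
    event = pmax(stats::rbinom(n, 1, 0.7), c(1, rep(0, n - 1))),
    x = matrix(stats::rnorm(n * p), n, p)
  )
}

# compact cohort for fast tests
small_cohort <- function(n = 52, seed = 1, ...) {
  generate_cohort(cohort_config(n = n, seed = seed, ...))
}
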