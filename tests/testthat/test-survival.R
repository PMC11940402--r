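test_that("Kaplan-Meier equals the empirical survival function without censoring", {
  km <- km_estimate(1:5, rep(1, 5))
  expect_equal(km$surv[km$time == 3], 0.4)
  expect_equal(km$median, 3)
  expect_true(km$median_defined)

  set.seed(21)
  for (rep in 1:10) {
    times <- round(rexp(sample(5:40, 1)), 6)
    times <- times + seq_along(times) * 1e-6  # untied
    km <- km_estimate(times, rep(1, length(times)))
    expect_equal(km$surv,
                 vapply(km$time, empirical_surv, numeric(1), times = times))
  }
})

test_that("degenerate curves are flagged, not fatal", {
  expect_warning(km <- km_estimate(c(2, 5, 9), c(0, 0, 0)), "censored")
  expect_false(km$median_defined)
  km1 <- km_estimate(4, 1)  # single event: S drops 1 -> 0 at t
  expect_equal(km1$surv, 0)
  expect_equal(km1$median, 4)
  expect_error(km_estimate(c(-1, 2), c(1, 1)), class = "gliomapd_domain_error")
  expect_error(km_estimate(c(1, 2), c(1, 2)), class = "gliomapd_domain_error")
})

test_that("cox_fit recovers a known two-group hazard ratio", {
  set.seed(31)
  n <- 5000
  grp <- rep(0:1, each = n / 2)
  time <- rexp(n, ifelse(grp == 1, 2, 1))
  fit <- cox_fit(data.frame(grp = grp), time, rep(1, n), "grp")
  expect_true(fit$converged)
  expect_gt(fit$table$hr, 1.9)
  expect_lt(fit$table$hr, 2.1)
  expect_true(fit$table$ci_lo < fit$table$hr & fit$table$hr < fit$table$ci_hi)
  expect_equal(fit$table$hr, exp(fit$table$coef))
})

test_that("cox_fit rejects constant covariates and missing columns", {
  d <- data.frame(x = rep(1, 10), y = rnorm(10))
  expect_error(cox_fit(d, rexp(10), rep(1, 10), "x"),
               class = "gliomapd_domain_error")
  expect_error(cox_fit(d, rexp(10), rep(1, 10), "z"),
               class = "gliomapd_schema_error")
  expect_error(cox_fit(d, rexp(10), rep(0, 10), "y"),
               class = "gliomapd_domain_error")
})

test_that("log-partial-likelihood matches the brute-force risk-set oracle", {
  set.seed(41)
  for (rep in 1:30) {
    p <- sample(1:2, 1)
    d <- random_tiny_surv(p = p)
    dat <- as.data.frame(d$x)
    names(dat) <- paste0("x", seq_len(p))
    fit <- tryCatch(cox_fit(dat, d$time, d$event, names(dat)),
                    error = function(e) NULL)
    if (is.null(fit) || !fit$converged) next  # separation on tiny data
    expect_lt(abs(fit$loglik -
                    logpl_oracle(d$time, d$event, d$x, fit$table$coef)),
              1e-8)
  }
})

test_that("separation is flagged rather than silently reported", {
  # perfectly separated: the early deaths are exactly the x = 1 group
  d <- data.frame(x = c(1, 1, 1, 0, 0, 0))
  fit <- cox_fit(d, c(1, 2, 3, 10, 11, 12), rep(1, 6), "x")
  expect_false(fit$converged)
  expect_gt(length(fit$flags), 0)
})

test_that("univariable screening keeps strong effects and passes nulls at alpha", {
  set.seed(51)
  n <- 5000
  d <- data.frame(grp = rep(0:1, each = n / 2), noise = rnorm(n))
  time <- rexp(n, ifelse(d$grp == 1, 2, 1))
  sc <- univariable_screen(d, time, rep(1, n), c("grp", "noise"))
  expect_true("grp" %in% sc$selected)
  expect_equal(sc$table$candidate, c("grp", "noise"))  # input order kept

  empty <- univariable_screen(d, time, rep(1, n), character(0))
  expect_identical(empty$selected, character(0))

  # type-I admission rate of a null covariate approaches alpha_screen
  set.seed(52)
  hits <- 0L
  for (rep in 1:1000) {
    m <- 120
    dd <- data.frame(x = rnorm(m))
    tt <- rexp(m)
    hits <- hits + (length(univariable_screen(dd, tt, rep(1, m), "x",
                                              alpha_screen = 0.2)$selected) > 0)
  }
  expect_gt(hits / 1000, 0.17)
  expect_lt(hits / 1000, 0.23)
})

test_that("Wald confidence intervals achieve nominal coverage", {
  set.seed(61)
  true_hr <- 1.8
  cover <- 0L
  for (rep in 1:500) {
    n <- 500
    grp <- rep(0:1, each = n / 2)
    time <- rexp(n, ifelse(grp == 1, true_hr, 1))
    fit <- cox_fit(data.frame(grp = grp), time, rep(1, n), "grp")
    cover <- cover + (fit$table$ci_lo <= true_hr & true_hr <= fit$table$ci_hi)
  }
  expect_gt(cover / 500, 0.93)
  expect_lt(cover / 500, 0.97)
})

test_that("stratified MGMT analysis recovers the planted effect layout", {
  # the spec's minimal default reading: effect only in the moderate stratum
  cfg <- cohort_config(n = 20000, seed = 2,
                       hr_os = c(1, 0.23, 1), hr_pfs = c(1, 0.18, 1))
  co <- generate_cohort(cfg)
  so <- stratified_mgmt_analysis(co, "baldock", "os")
  expect_equal(as.character(so$class),
               c("HIGHLY_DIFFUSE", "MODERATELY_DIFFUSE", "NODULAR"))
  expect_lt(abs(log(so$hr[2]) - log(0.23)), 0.1)
  expect_lt(abs(log(so$hr[1])), 0.1)  # HR ~ 1 where nothing was planted
  expect_lt(abs(log(so$hr[3])), 0.1)
  sp <- stratified_mgmt_analysis(co, "baldock", "pfs")
  # PFS hazard is floored at the OS hazard: effective planted moderate HR
  # is max(mu*0.18, lambda*0.23)/mu, still within the 0.1 log tolerance
  expect_lt(abs(log(sp$hr[2]) - log(0.18)), 0.1)
  expect_lt(abs(log(sp$hr[1])), 0.1)
  expect_lt(abs(log(sp$hr[3])), 0.1)
})

test_that("permuted MGMT labels give null stratum effects", {
  co <- small_cohort(n = 6000, seed = 71)
  set.seed(72)
  co$mgmt_pct <- sample(co$mgmt_pct)
  s <- stratified_mgmt_analysis(co, "baldock", "os")
  expect_true(all(abs(log(s$hr)) < 0.2))
})

test_that("degenerate strata are flagged, not fatal", {
  co <- generate_cohort(cohort_config(n = 300, seed = 81,
                                      class_probs = c(0, 1, 0)))
  s <- stratified_mgmt_analysis(co, "baldock", "os")
  expect_equal(nrow(s), 1)
  expect_equal(as.character(s$class), "MODERATELY_DIFFUSE")
  co$mgmt_pct <- rep(50, nrow(co))  # single MGMT level
  s2 <- stratified_mgmt_analysis(co, "baldock", "os")
  expect_equal(s2$flag, "single MGMT level")
  expect_true(is.na(s2$hr))
})
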