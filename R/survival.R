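#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator of the survival function under right censoring
#' (computed via [survival::survfit()]). With no censoring the estimate
#' equals the empirical survival function; the median is the smallest time
#' at which the curve reaches or falls below 1/2, and is flagged undefined
#' when the curve never does (e.g. all observations censored).
#'
#' @param time Follow-up times, months, > 0.
#' @param event Event indicators in `{0, 1}`.
#' @return Object of class `km_curve`: `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv`, `median`, `median_defined`, `n`, `n_events`.
#' @export
#' @examples
#' km_estimate(c(1, 2, 3, 4, 5), rep(1, 5))$median
km_estimate <- function(time, event) {
  check_surv(time, event)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.type = "none")
  q <- stats::quantile(fit, probs = 0.5)
  med <- unname(if (is.list(q)) q$quantile else q)
  defined <- !is.na(med)
  if (sum(event) == 0) {
    warning("all observations censored: survival curve is uninformative",
            call. = FALSE)
  }
  structure(list(
    time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
    n_censor = fit$n.censor, surv = fit$surv,
    median = med, median_defined = defined,
    n = length(time), n_events = sum(event)
  ), class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: n = %d, events = %d, median = %s\n",
              x$n, x$n_events,
              if (x$median_defined) sprintf("%.2f", x$median) else "undefined"))
  invisible(x)
}

check_surv <- function(time, event) {
  if (!is.numeric(time) || anyNA(time) || any(time <= 0)) {
    stop_domain("`time` must be numeric, non-missing and > 0")
  }
  if (anyNA(event) || !all(event %in% c(0, 1))) {
    stop_domain("`event` must contain only 0 and 1")
  }
  if (length(time) != length(event)) {
    stop_domain("`time` and `event` lengths differ")
  }
}

#' Cox proportional-hazards fit
#'
#' Maximizes the Cox partial likelihood (Efron tie correction by default) by
#' Newton-Raphson via [survival::coxph()], and reports per-covariate hazard
#' ratios with Wald 95% confidence intervals and p-values. Constant
#' covariates are rejected; non-convergence and monotone-likelihood
#' (complete separation) fits are returned flagged rather than silently.
#'
#' @param data Data frame holding the covariates.
#' @param time,event Survival outcome (columns of the model, passed as
#'   vectors; months and 0/1 indicators).
#' @param covariates Character vector of column names of `data` to enter the
#'   linear predictor. Factors expand to indicator contrasts against their
#'   first level.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return Object of class `cox_fit`: data frame `table` with columns
#'   `term`, `coef`, `hr`, `ci_lo`, `ci_hi`, `p`; plus `loglik` (at the
#'   optimum), `loglik_null`, `converged`, `flags`, `n`, `n_events`.
#' @export
cox_fit <- function(data, time, event, covariates, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  check_surv(time, event)
  if (sum(event) < 1) stop_domain("at least one event is required")
  if (!all(covariates %in% names(data))) {
    stop_schema(sprintf("covariate(s) not in `data`: %s",
                        paste(setdiff(covariates, names(data)), collapse = ", ")))
  }
  for (v in covariates) {
    if (length(unique(data[[v]])) < 2) {
      stop_domain(sprintf("covariate `%s` is constant across subjects", v))
    }
  }
  df <- data[, covariates, drop = FALSE]
  df$.time <- time; df$.event <- event
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", covariates), collapse = " + ")))
  flags <- character(0)
  fit <- withCallingHandlers(
    survival::coxph(fml, data = df, ties = ties),
    warning = function(w) {
      flags <<- c(flags, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  converged <- !anyNA(beta) && all(is.finite(se)) &&
    !any(grepl("converge|infinite|out of iterations|beta may be infinite", flags,
               ignore.case = TRUE))
  z <- beta / se
  tab <- data.frame(
    term = names(beta),
    coef = unname(beta),
    hr = exp(unname(beta)),
    ci_lo = exp(unname(beta - 1.96 * se)),
    ci_hi = exp(unname(beta + 1.96 * se)),
    p = unname(2 * stats::pnorm(-abs(z))),
    row.names = NULL
  )
  structure(list(table = tab,
                 loglik = fit$loglik[2], loglik_null = fit$loglik[1],
                 converged = converged, flags = flags,
                 ties = ties, n = fit$n, n_events = fit$nevent),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox proportional-hazards fit (%s ties): n = %d, events = %d%s\n",
              x$ties, x$n, x$n_events,
              if (x$converged) "" else " [NOT CONVERGED]"))
  tb <- x$table
  for (i in seq_len(nrow(tb))) {
    cat(sprintf("  %-24s HR %.3f (95%% CI %.3f-%.3f), p = %.4g\n",
                tb$term[i], tb$hr[i], tb$ci_lo[i], tb$ci_hi[i], tb$p[i]))
  }
  invisible(x)
}

#' Univariable screening of candidate covariates
#'
#' Fits each candidate alone against the endpoint and retains those with a
#' Wald p-value below `alpha_screen` (default 0.2, the conventional
#' univariable gate before a multivariable model), preserving input order.
#' A candidate whose univariable fit fails is excluded with a warning.
#'
#' @inheritParams cox_fit
#' @param candidates Character vector of candidate covariate names.
#' @param alpha_screen Screening level in (0, 1).
#' @return List with `selected` (names passing the screen) and `table`
#'   (per-candidate p-value and status).
#' @export
univariable_screen <- function(data, time, event, candidates,
                               alpha_screen = 0.2) {
  if (!is.numeric(alpha_screen) || alpha_screen <= 0 || alpha_screen >= 1) {
    stop_domain("`alpha_screen` must lie in (0, 1)")
  }
  if (length(candidates) == 0) {
    return(list(selected = character(0),
                table = data.frame(candidate = character(0), p = numeric(0),
                                   status = character(0))))
  }
  rows <- lapply(candidates, function(v) {
    fit <- tryCatch(cox_fit(data, time, event, v),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      warning(sprintf("univariable fit for `%s` failed (%s): excluded",
                      v, conditionMessage(fit)), call. = FALSE)
      return(data.frame(candidate = v, p = NA_real_, status = "failed"))
    }
    # smallest p over the expanded terms (single p for a single contrast)
    data.frame(candidate = v, p = min(fit$table$p),
               status = if (fit$converged) "ok" else "not_converged")
  })
  tab <- do.call(rbind, rows)
  sel <- tab$candidate[!is.na(tab$p) & tab$p < alpha_screen & tab$status == "ok"]
  list(selected = as.character(sel), table = tab)
}

#' Invasiveness-stratified MGMT effect
#'
#' Within each invasiveness class of a scored cohort, fits the univariable
#' proportional-hazards model for MGMT methylation (methylated vs
#' unmethylated) on the chosen endpoint - the stratified block of the
#' published analysis. Strata with no events or a single MGMT level are
#' flagged, not fatal.
#'
#' @param records Cohort data frame (internal mm^3 schema).
#' @param scheme Cutoff scheme for the invasiveness classification.
#' @param endpoint `"os"` or `"pfs"`.
#' @return Object of class `mgmt_strata`: data frame with one row per class
#'   present in the cohort (`class`, `n`, `n_events`, `hr`, `ci_lo`,
#'   `ci_hi`, `p`, `flag`) and the per-class `cox_fit` objects in
#'   `attr(, "fits")`.
#' @export
stratified_mgmt_analysis <- function(records, scheme = "baldock",
                                     endpoint = c("os", "pfs")) {
  endpoint <- match.arg(endpoint)
  cls <- classify_invasiveness(rho_over_d(records$vt1, records$vt2), scheme)
  status <- classify_mgmt(records$mgmt_pct)
  time <- records[[paste0(endpoint, "_months")]]
  event <- records[[paste0(endpoint, "_event")]]
  present <- INVASIVENESS_LEVELS[INVASIVENESS_LEVELS %in% levels(droplevels(cls))]
  fits <- list()
  rows <- lapply(present, function(cl) {
    idx <- cls == cl
    sub <- data.frame(mgmt = factor(status[idx],
                                    levels = c("UNMETHYLATED", "METHYLATED")))
    out <- data.frame(class = cl, n = sum(idx), n_events = sum(event[idx]),
                      hr = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                      p = NA_real_, flag = "")
    if (sum(event[idx]) == 0) {
      out$flag <- "no events"
      return(out)
    }
    if (length(unique(sub$mgmt)) < 2) {
      out$flag <- "single MGMT level"
      return(out)
    }
    fit <- cox_fit(sub, time[idx], event[idx], "mgmt")
    fits[[cl]] <<- fit
    out$hr <- fit$table$hr; out$ci_lo <- fit$table$ci_lo
    out$ci_hi <- fit$table$ci_hi; out$p <- fit$table$p
    if (!fit$converged) out$flag <- "not converged"
    out
  })
  tab <- do.call(rbind, rows)
  tab$class <- factor(tab$class, levels = INVASIVENESS_LEVELS)
  structure(tab, fits = fits, endpoint = endpoint,
            scheme = cutoff_scheme(scheme)$name,
            class = c("mgmt_strata", "data.frame"))
}

#' @export
print.mgmt_strata <- function(x, ...) {
  cat(sprintf("MGMT (methylated) effect by invasiveness class - endpoint %s, scheme '%s'\n",
              toupper(attr(x, "endpoint")), attr(x, "scheme")))
  for (i in seq_len(nrow(x))) {
    if (nzchar(x$flag[i])) {
      cat(sprintf("  %-20s n = %d [%s]\n", x$class[i], x$n[i], x$flag[i]))
    } else {
      cat(sprintf("  %-20s HR %.2f (95%% CI %.2f-%.2f), p = %.3f (n = %d)\n",
                  x$class[i], x$hr[i], x$ci_lo[i], x$ci_hi[i], x$p[i], x$n[i]))
    }
  }
  invisible(x)
}
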