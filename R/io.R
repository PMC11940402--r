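# Cohort CSV interchange. Volumes travel in cc at the file boundary and in
# mm^3 internally; the conversion factor is exactly 1000.

COHORT_COLUMNS <- c("patient_id", "age_years", "sex", "mgmt_pct", "location",
                    "side", "kps_pre", "kps_post", "vt1_cc", "vt2_cc",
                    "residual_ce_cc", "postop_flair_cc",
                    "os_months", "os_event", "pfs_months", "pfs_event")
NUMERIC_COLUMNS <- c("age_years", "mgmt_pct", "kps_pre", "kps_post", "vt1_cc",
                     "vt2_cc", "residual_ce_cc", "postop_flair_cc",
                     "os_months", "pfs_months")
EVENT_COLUMNS <- c("os_event", "pfs_event")
VOLUME_COLUMNS <- c(vt1 = "vt1_cc", vt2 = "vt2_cc",
                    residual_ce = "residual_ce_cc",
                    postop_flair = "postop_flair_cc")

#' Read a cohort CSV
#'
#' Reads the documented cohort schema (one row per patient, volumes in cc,
#' header required) and converts volumes to the internal mm^3 columns
#' (`vt1`, `vt2`, `residual_ce`, `postop_flair`). Schema violations -
#' missing required columns, non-numeric volumes, event flags outside
#' `{0, 1}` - raise errors naming the offending row and column. Unknown
#' extra columns are preserved with a warning.
#'
#' @param path Path to the CSV file.
#' @return A `pd_cohort` data frame in the internal schema.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop_schema(sprintf("no such file: %s", path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(raw) == 0) stop_schema(sprintf("empty cohort file: %s", path))
  missing <- setdiff(COHORT_COLUMNS, names(raw))
  if (length(missing)) {
    stop_schema(sprintf("missing required column(s): %s",
                        paste(missing, collapse = ", ")))
  }
  extra <- setdiff(names(raw), COHORT_COLUMNS)
  if (length(extra)) {
    warning(sprintf("unknown column(s) preserved and passed through: %s",
                    paste(extra, collapse = ", ")), call. = FALSE)
  }
  for (col in c(NUMERIC_COLUMNS, EVENT_COLUMNS)) {
    v <- raw[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(is.na(num) & !(is.na(v) | v == ""))
      if (length(bad)) {
        stop_schema(sprintf("non-numeric value '%s' in column `%s`, row %d",
                            v[bad[1]], col, bad[1]))
      }
      raw[[col]] <- num
    }
  }
  for (col in EVENT_COLUMNS) {
    bad <- which(!is.na(raw[[col]]) & !(raw[[col]] %in% c(0, 1)))
    if (length(bad)) {
      stop_schema(sprintf("event flag outside {0, 1} in column `%s`, row %d",
                          col, bad[1]))
    }
    raw[[col]] <- as.integer(raw[[col]])
  }
  for (col in VOLUME_COLUMNS) {
    bad <- which(!is.na(raw[[col]]) & raw[[col]] < 0)
    if (length(bad)) {
      stop_schema(sprintf("negative volume in column `%s`, row %d",
                          col, bad[1]))
    }
  }
  out <- raw
  for (nm in names(VOLUME_COLUMNS)) {
    out[[nm]] <- raw[[VOLUME_COLUMNS[nm]]] * 1000  # cc -> mm^3, exact
  }
  out <- out[, c(setdiff(COHORT_COLUMNS, VOLUME_COLUMNS),
                 names(VOLUME_COLUMNS), extra)]
  structure(out, class = c("pd_cohort", "data.frame"))
}

#' Write a cohort CSV
#'
#' Inverse of [read_cohort()]: converts internal mm^3 volumes back to cc and
#' writes the documented schema (plus any extra columns present). The write
#' then read round trip reproduces the records.
#'
#' @param records Cohort data frame in the internal schema.
#' @param path Output CSV path.
#' @export
write_cohort <- function(records, path) {
  out <- as.data.frame(records)
  for (nm in names(VOLUME_COLUMNS)) {
    out[[VOLUME_COLUMNS[nm]]] <- out[[nm]] / 1000
    out[[nm]] <- NULL
  }
  extra <- setdiff(names(out), COHORT_COLUMNS)
  out <- out[, c(COHORT_COLUMNS, extra)]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Score a cohort
#'
#' Augments a cohort with the computed per-patient results: rho/D ratio
#' (`rho_over_d_mm2`), invasiveness class under the selected scheme,
#' RANO-resect class, and MGMT status. Volumes are also exposed in cc
#' (`vt1_cc`, ...) for per-unit regression covariates.
#'
#' @param records Cohort data frame in the internal schema.
#' @param scheme Cutoff scheme (name or [cutoff_scheme()]).
#' @return The augmented data frame.
#' @export
score_cohort <- function(records, scheme = "baldock") {
  out <- as.data.frame(records)
  out$rho_over_d_mm2 <- rho_over_d(out$vt1, out$vt2)
  out$invasiveness_class <- classify_invasiveness(out$rho_over_d_mm2, scheme)
  out$rano_class <- classify_rano_resect(out$residual_ce, out$postop_flair)
  out$mgmt_status <- classify_mgmt(out$mgmt_pct)
  for (nm in names(VOLUME_COLUMNS)) out[[VOLUME_COLUMNS[nm]]] <- out[[nm]] / 1000
  structure(out, class = c("pd_cohort", "data.frame"))
}

#' End-to-end run configuration
#'
#' @param seed Integer seed driving every random draw of the run.
#' @param n Cohort size when generating (ignored when `cohort` is given).
#' @param scheme Invasiveness cutoff scheme.
#' @param screen_alpha Univariable screening level.
#' @param cohort Optional path to an existing cohort CSV; when `NULL` a
#'   synthetic cohort is generated.
#' @param out Optional output directory for the results bundle.
#' @param cohort_overrides Named list of [cohort_config()] arguments
#'   overriding the defaults of the generator.
#' @return Object of class `run_config`.
#' @export
run_config <- function(seed = 1L, n = 52L, scheme = "baldock",
                       screen_alpha = 0.2, cohort = NULL, out = NULL,
                       cohort_overrides = list()) {
  sc <- cutoff_scheme(scheme)
  structure(list(seed = as.integer(seed), n = as.integer(n), scheme = sc,
                 screen_alpha = screen_alpha, cohort = cohort, out = out,
                 cohort_overrides = cohort_overrides),
            class = "run_config")
}

SCREEN_CANDIDATES <- c("vt1_cc", "vt2_cc", "postop_flair_cc", "mgmt_status",
                       "kps_post", "age_years", "sex", "location",
                       "invasiveness_class")

analyze_endpoint <- function(scored, endpoint, screen_alpha) {
  time <- scored[[paste0(endpoint, "_months")]]
  event <- scored[[paste0(endpoint, "_event")]]
  screen <- univariable_screen(scored, time, event, SCREEN_CANDIDATES,
                               screen_alpha)
  uni <- lapply(SCREEN_CANDIDATES, function(v) {
    tryCatch(cox_fit(scored, time, event, v), error = function(e) NULL)
  })
  names(uni) <- SCREEN_CANDIDATES
  multi <- if (length(screen$selected) >= 1) {
    cox_fit(scored, time, event, screen$selected)
  } else NULL
  strat <- stratified_mgmt_analysis(scored, attr(scored, "scheme") %||% "baldock",
                                    endpoint)
  list(endpoint = endpoint, univariable = uni, screen = screen,
       multivariable = multi, stratified = strat)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

km_table <- function(scored, endpoint) {
  cls <- scored$invasiveness_class
  status <- scored$mgmt_status
  time <- scored[[paste0(endpoint, "_months")]]
  event <- scored[[paste0(endpoint, "_event")]]
  combos <- expand.grid(class = levels(cls), mgmt = levels(status),
                        stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    idx <- cls == combos$class[i] & status == combos$mgmt[i]
    if (!any(idx) || sum(event[idx]) == 0) return(NULL)
    km <- km_estimate(time[idx], event[idx])
    data.frame(endpoint = endpoint, class = combos$class[i],
               mgmt = combos$mgmt[i], time = km$time, n_risk = km$n_risk,
               n_event = km$n_event, surv = km$surv)
  })
  do.call(rbind, rows)
}

#' Run the full analysis pipeline
#'
#' Chains cohort acquisition (generation or CSV), scoring, descriptive
#' summary, univariable screening, multivariable modeling, the
#' invasiveness-stratified MGMT analysis for both endpoints, and per-stratum
#' Kaplan-Meier curve tables. Deterministic given the configured seed; when
#' `config$out` is set the bundle is also written to disk.
#'
#' @param config A [run_config()].
#' @return Object of class `results_bundle` (invisibly when writing).
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  log_stage <- function(stage, msg) {
    message(sprintf("[%s] %s", stage, msg))
  }
  if (!is.null(config$cohort)) {
    log_stage("input", paste("reading cohort from", config$cohort))
    records <- read_cohort(config$cohort)
  } else {
    log_stage("generate", sprintf("synthetic cohort n = %d, seed = %d",
                                  config$n, config$seed))
    args <- utils::modifyList(list(n = config$n, seed = config$seed),
                              config$cohort_overrides)
    records <- generate_cohort(do.call(cohort_config, args))
  }
  log_stage("score", sprintf("scheme '%s'", config$scheme$name))
  scored <- score_cohort(records, config$scheme)
  attr(scored, "scheme") <- config$scheme$name
  summary <- summarize_cohort(records, config$scheme)
  log_stage("analyze", "survival inference (OS, PFS)")
  analyses <- lapply(c("os", "pfs"), analyze_endpoint,
                     scored = scored, screen_alpha = config$screen_alpha)
  names(analyses) <- c("os", "pfs")
  km <- do.call(rbind, lapply(c("os", "pfs"), km_table, scored = scored))
  bundle <- structure(list(
    summary = summary,
    analyses = analyses,
    km_curves = km,
    cohort = scored,
    provenance = list(
      package = "gliomapd",
      version = as.character(utils::packageVersion("gliomapd")),
      seed = config$seed, n = nrow(scored),
      scheme = config$scheme$name,
      screen_alpha = config$screen_alpha,
      cohort_source = config$cohort %||% "synthetic",
      cohort_overrides = config$cohort_overrides
    )
  ), class = "results_bundle")
  if (!is.null(config$out)) {
    log_stage("write", config$out)
    write_results(bundle, config$out)
  }
  invisible(bundle)
}

serialize_fit <- function(fit) {
  if (is.null(fit)) return(NULL)
  list(table = fit$table, loglik = fit$loglik, loglik_null = fit$loglik_null,
       converged = fit$converged, ties = fit$ties, n = fit$n,
       n_events = fit$n_events)
}

#' Write a results bundle to a directory
#'
#' Emits the scored cohort (`cohort.csv`), the descriptive summary
#' (`summary.json`), per-endpoint fit tables shaped like the published
#' univariable / multivariable / stratified blocks (`fits_os.json`,
#' `fits_pfs.json`), the Kaplan-Meier curve tables (`km_curves.csv`), and a
#' provenance block (`provenance.json`) from which the whole bundle is
#' reproducible.
#'
#' @param bundle A `results_bundle` from [run_pipeline()].
#' @param dir Output directory (created if absent).
#' @export
write_results <- function(bundle, dir) {
  stopifnot(inherits(bundle, "results_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_cohort(bundle$cohort, file.path(dir, "cohort.csv"))
  jsonlite::write_json(unclass(bundle$summary),
                       file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  for (ep in names(bundle$analyses)) {
    a <- bundle$analyses[[ep]]
    jsonlite::write_json(list(
      endpoint = ep,
      univariable = lapply(a$univariable, serialize_fit),
      screen = a$screen,
      multivariable = serialize_fit(a$multivariable),
      stratified = as.data.frame(a$stratified)
    ), file.path(dir, sprintf("fits_%s.json", ep)),
    auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  if (!is.null(bundle$km_curves)) {
    utils::write.csv(bundle$km_curves, file.path(dir, "km_curves.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(bundle$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.results_bundle <- function(x, ...) {
  cat("gliomapd results bundle\n")
  cat(sprintf("  cohort: n = %d (%s, seed %d)\n", x$provenance$n,
              x$provenance$cohort_source, x$provenance$seed))
  print(x$summary)
  for (ep in names(x$analyses)) {
    print(x$analyses[[ep]]$stratified)
  }
  invisible(x)
}
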