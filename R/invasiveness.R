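#' Equivalent-sphere radius of a volume
#'
#' Radius of the sphere with the given volume, `(3 V / 4 pi)^(1/3)`. Tumor
#' volumes measured on MRI are reduced to equivalent-sphere radii before the
#' invisible-margin width is computed.
#'
#' @param volume Volume(s) in mm^3; must be non-negative.
#' @return Radius (mm), same length as `volume`.
#' @seealso [sphere_volume()] for the inverse.
#' @export
#' @examples
#' equivalent_sphere_radius(4 * pi / 3) # unit sphere
equivalent_sphere_radius <- function(volume) {
  if (!is.numeric(volume) || anyNA(volume)) {
    stop_domain("`volume` must be numeric and non-missing")
  }
  if (any(volume < 0)) {
    stop_domain("volumes must be >= 0")
  }
  (3 * volume / (4 * pi))^(1 / 3)
}

#' @rdname equivalent_sphere_radius
#' @param radius Radius (mm), non-negative.
#' @export
sphere_volume <- function(radius) {
  if (!is.numeric(radius) || anyNA(radius) || any(radius < 0)) {
    stop_domain("`radius` must be numeric and >= 0")
  }
  (4 * pi / 3) * radius^3
}

#' Width (mm) of the invisible infiltrative margin implied by the model,
#' in units of sqrt(D/rho). The contrast-enhancing rim is taken at 80% of
#' carrying capacity and the FLAIR rim at 16%; for the travelling-wave profile
#' of the proliferation-diffusion model the shell between them has width
#' MARGIN_CONSTANT * sqrt(D/rho).
#' @keywords internal
MARGIN_CONSTANT <- 6.106

#' Proliferation/diffusion ratio from imaging volumes
#'
#' Invasiveness index of a contrast-enhancing glioma from its preoperative
#' contrast-enhancing (CE, `vt1`) and T2/FLAIR (`vt2`) tumor volumes:
#'
#' \deqn{\rho/D = (4\pi/3)^{2/3} \left(\frac{6.106}{V_{T2}^{1/3} - V_{T1}^{1/3}}\right)^2}
#'
#' equivalently `(6.106 / (r2 - r1))^2` with equivalent-sphere radii. The
#' difference `r2 - r1` is the visible part of the infiltrative margin; under
#' the proliferation-diffusion growth model its width is
#' `6.106 * sqrt(D/rho)`, so a narrow margin means a nodular (high rho/D)
#' tumor and a wide margin a diffuse (low rho/D) one.
#'
#' @param vt1 Preoperative contrast-enhancing volume(s), mm^3, strictly
#'   positive (non-enhancing tumors are not scoreable).
#' @param vt2 Preoperative T2/FLAIR volume(s), mm^3; must exceed `vt1`.
#' @return rho/D ratio(s) in mm^-2.
#' @export
#' @examples
#' rho_over_d(31400, 79900) # cohort-mean volumes, about 0.73 mm^-2
rho_over_d <- function(vt1, vt2) {
  if (!is.numeric(vt1) || !is.numeric(vt2) || anyNA(vt1) || anyNA(vt2)) {
    stop_domain("`vt1` and `vt2` must be numeric and non-missing")
  }
  if (any(vt1 <= 0)) {
    stop_domain("`vt1` must be > 0: non-enhancing tumors cannot be scored")
  }
  if (any(vt2 <= vt1)) {
    stop_margin("`vt2` must exceed `vt1`: no measurable invisible margin")
  }
  (4 * pi / 3)^(2 / 3) * (MARGIN_CONSTANT / (vt2^(1 / 3) - vt1^(1 / 3)))^2
}

#' Invert the rho/D ratio for the FLAIR volume
#'
#' Closed-form inverse of [rho_over_d()] in its second argument: the unique
#' `vt2 > vt1` whose margin width matches the requested ratio,
#' `r2 = r1 + 6.106 / sqrt(ratio)`. Used by the cohort generator to plant a
#' target invasiveness class exactly.
#'
#' @param vt1 Contrast-enhancing volume(s), mm^3, > 0.
#' @param ratio Target rho/D ratio(s), mm^-2, > 0.
#' @return FLAIR volume(s) `vt2` in mm^3.
#' @export
invert_rho_over_d <- function(vt1, ratio) {
  if (!is.numeric(vt1) || !is.numeric(ratio) || anyNA(vt1) || anyNA(ratio)) {
    stop_domain("`vt1` and `ratio` must be numeric and non-missing")
  }
  if (any(vt1 <= 0) || any(ratio <= 0)) {
    stop_domain("`vt1` and `ratio` must be > 0")
  }
  r1 <- equivalent_sphere_radius(vt1)
  sphere_volume(r1 + MARGIN_CONSTANT / sqrt(ratio))
}

#' Invasiveness cutoff schemes
#'
#' The literature carries no consensus cutoffs; two published schemes are
#' built in. `"baldock"` (the default throughout the package) uses
#' 0.55 / 1.80 mm^-2, `"alternative"` uses 0.38 / 1.30 mm^-2. A custom scheme
#' may be built by passing `low` and `high` directly.
#'
#' @param scheme `"baldock"`, `"alternative"`, or an arbitrary name when
#'   `low`/`high` are supplied.
#' @param low,high Custom class boundaries in mm^-2, `0 < low < high`.
#' @return An object of class `cutoff_scheme`: list with `name`, `low`, `high`.
#' @export
cutoff_scheme <- function(scheme = c("baldock", "alternative"),
                          low = NULL, high = NULL) {
  if (inherits(scheme, "cutoff_scheme")) return(scheme)
  if (is.null(low) != is.null(high)) {
    stop_domain("supply both `low` and `high`, or neither")
  }
  if (is.null(low)) {
    scheme <- match.arg(scheme)
    bounds <- switch(scheme,
      baldock     = c(0.55, 1.80),
      alternative = c(0.38, 1.30)
    )
    low <- bounds[1]; high <- bounds[2]
  } else {
    if (!is.character(scheme) || length(scheme) != 1) {
      stop_domain("custom schemes need a single-string name")
    }
  }
  if (!(is.finite(low) && is.finite(high) && 0 < low && low < high)) {
    stop_domain("cutoffs must satisfy 0 < low < high")
  }
  structure(list(name = scheme, low = low, high = high),
            class = "cutoff_scheme")
}

#' @export
print.cutoff_scheme <- function(x, ...) {
  cat(sprintf("cutoff scheme '%s': highly diffuse < %g <= moderate <= %g < nodular (mm^-2)\n",
              x$name, x$low, x$high))
  invisible(x)
}

INVASIVENESS_LEVELS <- c("HIGHLY_DIFFUSE", "MODERATELY_DIFFUSE", "NODULAR")

#' Classify tumor invasiveness from the rho/D ratio
#'
#' Partitions `(0, Inf)` into highly diffuse / moderately diffuse / nodular
#' under a cutoff scheme. The published cutoffs are stated without bracket
#' semantics; by default both boundary values fall in the moderate class
#' (closed middle interval). Set `boundaries = "outer"` to assign them
#' outward instead.
#'
#' @param ratio rho/D ratio(s), mm^-2, > 0.
#' @param scheme A [cutoff_scheme()] or its name.
#' @param boundaries `"moderate"` (default: closed middle interval) or
#'   `"outer"` (boundary values go to the adjacent outer class).
#' @return Ordered factor with levels `HIGHLY_DIFFUSE < MODERATELY_DIFFUSE <
#'   NODULAR`.
#' @export
#' @examples
#' classify_invasiveness(c(0.4, 1.0, 2.0))
#' classify_invasiveness(0.4, scheme = "alternative")
classify_invasiveness <- function(ratio, scheme = "baldock",
                                  boundaries = c("moderate", "outer")) {
  boundaries <- match.arg(boundaries)
  sc <- cutoff_scheme(scheme)
  if (!is.numeric(ratio) || anyNA(ratio)) {
    stop_domain("`ratio` must be numeric and non-missing")
  }
  if (any(ratio <= 0) || any(!is.finite(ratio))) {
    stop_domain("`ratio` must be finite and > 0")
  }
  cls <- if (boundaries == "moderate") {
    ifelse(ratio < sc$low, 1L, ifelse(ratio <= sc$high, 2L, 3L))
  } else {
    ifelse(ratio <= sc$low, 1L, ifelse(ratio < sc$high, 2L, 3L))
  }
  factor(INVASIVENESS_LEVELS[cls], levels = INVASIVENESS_LEVELS, ordered = TRUE)
}

#' Extent-of-resection class under the 2022 RANO-resect scheme
#'
#' `SUPR` (supramaximal): no residual contrast-enhancing (CE) tumor and
#' postoperative FLAIR volume below 5 cm^3. `CR` (complete): no residual CE
#' but FLAIR >= 5 cm^3. `NTR` (near-total): residual CE present. The source
#' scheme names NTR only for residual CE > 1 cm^3 and leaves (0, 1] cm^3
#' unnamed; this implementation maps any positive residual CE to NTR and
#' warns when a value falls in the unnamed gap.
#'
#' @param residual_ce Postoperative residual CE volume(s), mm^3, >= 0.
#'   Compared against exactly zero (volumetry input is user-asserted).
#' @param postop_flair Postoperative residual FLAIR volume(s), mm^3, >= 0.
#' @return Factor with levels `SUPR`, `CR`, `NTR`.
#' @export
classify_rano_resect <- function(residual_ce, postop_flair) {
  if (!is.numeric(residual_ce) || !is.numeric(postop_flair) ||
      anyNA(residual_ce) || anyNA(postop_flair)) {
    stop_domain("volumes must be numeric and non-missing")
  }
  if (any(residual_ce < 0) || any(postop_flair < 0)) {
    stop_domain("volumes must be >= 0")
  }
  gap <- residual_ce > 0 & residual_ce <= 1000
  if (any(gap)) {
    warning(sprintf(paste0(
      "%d residual CE volume(s) in (0, 1000] mm^3 fall in the unnamed gap ",
      "of the RANO-resect definitions; mapped to NTR"), sum(gap)),
      call. = FALSE)
  }
  out <- ifelse(residual_ce > 0, "NTR",
                ifelse(postop_flair < 5000, "SUPR", "CR"))
  factor(out, levels = c("SUPR", "CR", "NTR"))
}

#' MGMT promoter methylation status
#'
#' Dichotomizes a pyrosequencing methylation percentage at 5%: values
#' strictly above 5% are `METHYLATED`, values at or below 5% are
#' `UNMETHYLATED`.
#'
#' @param methylation_pct Percentage(s) in \[0, 100\].
#' @return Factor with levels `UNMETHYLATED`, `METHYLATED` (unmethylated
#'   first, so it is the reference level in regression contrasts).
#' @export
classify_mgmt <- function(methylation_pct) {
  if (!is.numeric(methylation_pct) || anyNA(methylation_pct)) {
    stop_domain("`methylation_pct` must be numeric and non-missing")
  }
  if (any(methylation_pct < 0 | methylation_pct > 100)) {
    stop_domain("`methylation_pct` must lie in [0, 100]")
  }
  factor(ifelse(methylation_pct > 5, "METHYLATED", "UNMETHYLATED"),
         levels = c("UNMETHYLATED", "METHYLATED"))
}

# classed conditions -----------------------------------------------------

stop_domain <- function(msg) {
  stop(errorCondition(msg, class = c("gliomapd_domain_error", "error")))
}

stop_margin <- function(msg) {
  stop(errorCondition(msg, class = c("gliomapd_margin_error",
                                     "gliomapd_domain_error", "error")))
}

stop_config <- function(msg) {
  stop(errorCondition(msg, class = c("gliomapd_config_error", "error")))
}

stop_schema <- function(msg) {
  stop(errorCondition(msg, class = c("gliomapd_schema_error", "error")))
}
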