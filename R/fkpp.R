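#' Parameters for the radial proliferation-diffusion simulation
#'
#' Configuration of the radially symmetric Fisher-KPP model
#' \deqn{\partial_t n = D \frac{1}{r^2}\partial_r (r^2 \partial_r n) + \rho\, n (1 - n)}
#' with normalized cell density `n` (fraction of carrying capacity),
#' zero-flux boundaries at `r = 0` and `r = domain_radius`, and a Gaussian
#' seed of amplitude `init_amplitude` and length scale `init_radius` at the
#' origin. An established front travels at asymptotic speed `2 sqrt(D rho)`
#' with a rigid profile of width proportional to `sqrt(D/rho)`.
#'
#' Defaults are sized from the physics: the grid resolves the intrinsic
#' front width `sqrt(D/rho)` with at least 8 cells (capped at 0.5 mm), the
#' horizon lets the front travel about 60 mm past the transient, and the
#' domain leaves 15 mm of headroom beyond the expected final front position.
#' The explicit time step must satisfy the stability bound
#' `dt <= grid_spacing^2 / (6 D)`.
#'
#' @param D Diffusion coefficient, mm^2/year.
#' @param rho Net proliferation rate, 1/year.
#' @param domain_radius Outer radius of the computational domain, mm.
#' @param grid_spacing Radial grid spacing, mm.
#' @param dt Time step, years. Default: the stability bound.
#' @param t_end Final time, years.
#' @param init_radius Length scale of the initial Gaussian bump, mm.
#' @param init_amplitude Peak of the initial bump, fraction of carrying
#'   capacity in (0, 1].
#' @param n_snapshots Number of stored density profiles (evenly spaced in
#'   time).
#' @return Object of class `pd_params`.
#' @export
pd_params <- function(D, rho,
                      domain_radius = NULL,
                      grid_spacing = NULL,
                      dt = NULL,
                      t_end = NULL,
                      init_radius = 2,
                      init_amplitude = 0.8,
                      n_snapshots = 40) {
  for (nm in c("D", "rho", "init_radius", "init_amplitude")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0) {
      stop_config(sprintf("`%s` must be a single positive number", nm))
    }
  }
  if (init_amplitude > 1) stop_config("`init_amplitude` must be <= 1")
  width <- sqrt(D / rho)
  if (is.null(grid_spacing)) grid_spacing <- min(0.5, width / 8)
  if (is.null(t_end)) t_end <- 60 / (2 * sqrt(D * rho)) + 10 / rho
  if (is.null(domain_radius)) {
    domain_radius <- init_radius + 2 * sqrt(D * rho) * t_end + 15
  }
  if (is.null(dt)) dt <- grid_spacing^2 / (6 * D)
  for (nm in c("domain_radius", "grid_spacing", "dt", "t_end")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0) {
      stop_config(sprintf("`%s` must be a single positive number", nm))
    }
  }
  bound <- grid_spacing^2 / (6 * D)
  if (dt > bound * (1 + 1e-12)) {
    stop_config(sprintf(
      "explicit scheme unstable: dt = %g exceeds the stability bound dt <= grid_spacing^2/(6 D) = %g",
      dt, bound))
  }
  if (init_radius >= domain_radius / 4) {
    stop_config("`init_radius` must be < domain_radius / 4")
  }
  structure(list(D = D, rho = rho, domain_radius = domain_radius,
                 grid_spacing = grid_spacing, dt = dt, t_end = t_end,
                 init_radius = init_radius, init_amplitude = init_amplitude,
                 n_snapshots = as.integer(n_snapshots)),
            class = "pd_params")
}

#' Simulate radial Fisher-KPP tumor growth
#'
#' Integrates the radially symmetric proliferation-diffusion equation with a
#' conservative finite-volume discretization (cell-centered on shells, exact
#' shell volumes, zero-flux at the origin and the outer boundary) and
#' explicit Euler time stepping. The finite-volume form conserves total cell
#' mass exactly when `rho = 0`.
#'
#' @param params A [pd_params()] object.
#' @return Object of class `pd_simulation`: list with `radii` (grid nodes,
#'   mm), `times` (snapshot times, years), `density` (matrix, one row per
#'   snapshot), and `params`.
#' @export
#' @examples
#' sim <- simulate_radial_fkpp(pd_params(D = 10, rho = 10, t_end = 0.5))
simulate_radial_fkpp <- function(params) {
  if (!inherits(params, "pd_params")) {
    stop_config("`params` must be built with pd_params()")
  }
  h <- params$grid_spacing
  r <- seq(0, params$domain_radius, by = h)
  N <- length(r)
  rf <- r + h / 2                       # cell faces; last face = outer boundary
  area <- 4 * pi * rf^2                 # face areas
  vol <- (4 * pi / 3) * (rf^3 - c(0, rf[-N]^3))  # exact shell volumes
  u <- params$init_amplitude * exp(-(r / params$init_radius)^2)

  nsteps <- ceiling(params$t_end / params$dt)
  dt <- params$t_end / nsteps
  snap_at <- unique(round(seq(1, nsteps, length.out = params$n_snapshots)))
  density <- matrix(NA_real_, length(snap_at), N)
  D <- params$D; rho <- params$rho
  k <- 1L
  for (s in seq_len(nsteps)) {
    flux <- D * area[-N] * diff(u) / h  # inward-positive flux at interior faces
    u <- u + dt * ((c(flux, 0) - c(0, flux)) / vol + rho * u * (1 - u))
    if (s == snap_at[k]) {
      density[k, ] <- u
      k <- k + 1L
    }
  }
  if (min(density) < -1e-9 || max(density) > 1 + 1e-9) {
    warning("density left [0, 1] beyond discretization slack", call. = FALSE)
  }
  if (u[N] > 1e-3) {
    warning("front reached the outer boundary: profile truncated; enlarge domain_radius",
            call. = FALSE)
  }
  structure(list(radii = r, times = snap_at * dt, density = density,
                 params = params),
            class = "pd_simulation")
}

#' @export
print.pd_simulation <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "radial Fisher-KPP simulation: D = %g mm^2/yr, rho = %g /yr (rho/D = %.4g mm^-2)\n",
    p$D, p$rho, p$rho / p$D))
  cat(sprintf("  grid: %d nodes, h = %g mm, domain %g mm; %d snapshots to t = %g yr\n",
              length(x$radii), p$grid_spacing, p$domain_radius,
              length(x$times), p$t_end))
  invisible(x)
}

snapshot_index <- function(sim, t) {
  i <- which.min(abs(sim$times - t))
  if (abs(sim$times[i] - t) > diff(range(sim$times)) / length(sim$times) + 1e-9) {
    warning(sprintf("no snapshot near t = %g; using nearest at t = %g",
                    t, sim$times[i]), call. = FALSE)
  }
  i
}

#' Radius at which the density profile crosses a threshold
#'
#' Finds where the radial profile at snapshot time `t` first falls below
#' `frac`, linearly interpolating between adjacent grid nodes. If the profile
#' never reaches `frac`, returns `NA` (the structure is not imageable at that
#' threshold). A profile that crosses the threshold more than once is
#' rejected with an ambiguity error reporting all crossings.
#'
#' @param sim A `pd_simulation`.
#' @param t Snapshot time, years (nearest stored snapshot is used).
#' @param frac Density threshold, fraction of carrying capacity in (0, 1).
#' @return Crossing radius in mm, or `NA_real_` when the profile stays below
#'   `frac` everywhere.
#' @export
extract_threshold_radius <- function(sim, t, frac) {
  stopifnot(inherits(sim, "pd_simulation"))
  if (!is.numeric(frac) || length(frac) != 1 || frac <= 0 || frac >= 1) {
    stop_domain("`frac` must lie strictly between 0 and 1")
  }
  u <- sim$density[snapshot_index(sim, t), ]
  above <- u >= frac
  if (!above[1]) return(NA_real_)      # never reaches the threshold
  flips <- which(diff(above) != 0)
  if (length(flips) == 0) return(NA_real_)  # above everywhere (front at boundary)
  if (length(flips) > 1) {
    r_all <- vapply(flips, function(i) {
      sim$radii[i] + (u[i] - frac) / (u[i] - u[i + 1]) * sim$params$grid_spacing
    }, numeric(1))
    stop(errorCondition(
      sprintf("profile crosses %g at %d radii (%s): non-monotone at the crossing",
              frac, length(r_all), paste(sprintf("%.3f", r_all), collapse = ", ")),
      class = c("gliomapd_ambiguous_crossing", "error")))
  }
  i <- flips[1]
  sim$radii[i] + (u[i] - frac) / (u[i] - u[i + 1]) * sim$params$grid_spacing
}

#' Virtual MRI volumes from a simulated tumor
#'
#' Applies the imaging assumption of the proliferation-diffusion framework to
#' a simulated density profile: the contrast-enhancing rim sits where cell
#' density crosses 80% of carrying capacity and the FLAIR rim where it
#' crosses 16%. Radii are converted to spherical volumes.
#'
#' @param sim A `pd_simulation`.
#' @param t Snapshot time, years.
#' @param thresholds Two density fractions `c(t1, t2)` with `t1 > t2`;
#'   defaults `c(0.80, 0.16)`.
#' @return Object of class `virtual_imaging`: list with `r_t1`, `r_t2` (mm),
#'   `vt1`, `vt2` (mm^3), `t`, and logical `imageable` (`FALSE`, with `NA`
#'   radii, while the lesion has not yet reached the inner threshold
#'   anywhere).
#' @export
virtual_imaging <- function(sim, t, thresholds = c(0.80, 0.16)) {
  stopifnot(inherits(sim, "pd_simulation"))
  if (length(thresholds) != 2 || thresholds[1] <= thresholds[2]) {
    stop_domain("`thresholds` must be two fractions with t1 > t2")
  }
  r1 <- extract_threshold_radius(sim, t, thresholds[1])
  r2 <- extract_threshold_radius(sim, t, thresholds[2])
  imageable <- !is.na(r1) && !is.na(r2)
  structure(list(
    r_t1 = r1, r_t2 = r2,
    vt1 = if (imageable) sphere_volume(r1) else NA_real_,
    vt2 = if (imageable) sphere_volume(r2) else NA_real_,
    t = t, thresholds = thresholds, imageable = imageable
  ), class = "virtual_imaging")
}

#' Estimate rho/D from virtual imaging
#'
#' Runs the imaging-based estimator ([rho_over_d()]) on the virtual volumes
#' of a simulated tumor. Comparing the result against the simulation's true
#' `rho/D` constitutes the estimator-validation experiment; the systematic
#' factor between the two is `(6.106 / c_sim)^2` where `c_sim` is the margin
#' constant the simulated dynamics imply (see [implied_constant()]).
#'
#' @param vi A [virtual_imaging()] result with `imageable = TRUE`.
#' @return Estimated rho/D in mm^-2.
#' @export
recover_ratio <- function(vi) {
  stopifnot(inherits(vi, "virtual_imaging"))
  if (!vi$imageable) {
    stop(errorCondition("lesion not yet imageable: no 80% crossing",
                        class = c("gliomapd_not_imageable", "error")))
  }
  rho_over_d(vi$vt1, vi$vt2)
}

#' Nondimensional margin constant implied by the simulation
#'
#' Width of the shell between the FLAIR-threshold and CE-threshold radii in
#' units of `sqrt(D/rho)`: `(r_t2 - r_t1) * sqrt(rho/D)`. For an established
#' travelling wave this is a pure number, to be compared against the 6.106
#' prefactor used by the imaging-based estimator. A warning is issued while
#' the front has travelled less than `10 sqrt(D/rho)` from the seed (pulled
#' fronts relax slowly, so early estimates are unreliable).
#'
#' @param sim A `pd_simulation`.
#' @param t Snapshot time, years.
#' @return The dimensionless margin constant.
#' @export
implied_constant <- function(sim, t) {
  stopifnot(inherits(sim, "pd_simulation"))
  p <- sim$params
  vi <- virtual_imaging(sim, t)
  if (!vi$imageable) {
    stop(errorCondition("lesion not yet imageable at both thresholds",
                        class = c("gliomapd_not_imageable", "error")))
  }
  travelled <- vi$r_t2 - p$init_radius
  if (travelled < 10 * sqrt(p$D / p$rho)) {
    warning("front has travelled < 10 sqrt(D/rho) from the seed: transient not elapsed, estimate unreliable",
            call. = FALSE)
  }
  (vi$r_t2 - vi$r_t1) * sqrt(p$rho / p$D)
}

#' Empirical front speed of a simulated tumor
#'
#' Speed of the `frac`-level set measured between two late snapshots
#' (the last snapshot and the one `lag` snapshots earlier). On an
#' established wave this converges to the asymptotic speed
#' `2 sqrt(D rho)` from below.
#'
#' @param sim A `pd_simulation`.
#' @param frac Level-set density; default 0.5.
#' @param lag Snapshot separation used for the finite difference.
#' @return Speed in mm/year.
#' @export
front_speed <- function(sim, frac = 0.5, lag = 4) {
  stopifnot(inherits(sim, "pd_simulation"))
  n <- length(sim$times)
  if (lag >= n) stop_domain("`lag` must be smaller than the number of snapshots")
  ra <- extract_threshold_radius(sim, sim$times[n - lag], frac)
  rb <- extract_threshold_radius(sim, sim$times[n], frac)
  if (is.na(ra) || is.na(rb)) {
    stop(errorCondition("front not established at the requested level",
                        class = c("gliomapd_not_imageable", "error")))
  }
  (rb - ra) / (sim$times[n] - sim$times[n - lag])
}
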