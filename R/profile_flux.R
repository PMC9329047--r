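# Pore-water and microsensor depth-profile handling: gradient fitting,
# Fickian diffusive flux, subsurface-peak partitioning, feature extraction.
#
# Coordinate convention: depth in m, positive downward, sediment-water
# interface (SWI) at 0; overlying-water points carry negative depths.
# Gradient windows are half-open [top, bottom). Flux sign: positive
# downward, so a concentration increasing with depth yields a negative
# (upward, toward-SWI) flux.

#' Depth profile of one solute in one core
#'
#' @param depths Depths in m, strictly increasing; negative values denote
#'   overlying-water points above the SWI.
#' @param concentrations Concentrations in mmol m-3 (numerically equal to
#'   micromolar), same length as `depths`. Negative values are floored to 0
#'   with a warning (below-detection readings).
#' @param species Solute name (`"O2"`, `"SumH2S"`, `"dFe"`, `"dAs"`,
#'   `"pH"`, ...). pH profiles store pH units in `concentrations`.
#' @param core_id,campaign Identifiers carried through to results.
#' @param detection_limit Detection limit in mmol m-3, or NA.
#' @return An object of class `depth_profile`.
#' @export
depth_profile <- function(depths, concentrations, species,
                          core_id = "core1", campaign = NA_character_,
                          detection_limit = NA_real_) {
  stopifnot(is.numeric(depths), is.numeric(concentrations))
  if (length(depths) != length(concentrations)) {
    stop("depths and concentrations must have equal length", call. = FALSE)
  }
  if (length(depths) < 2) {
    stop("a depth profile needs at least 2 points", call. = FALSE)
  }
  if (any(diff(depths) <= 0)) {
    stop("depths must be strictly increasing (core ", core_id, ")",
         call. = FALSE)
  }
  if (anyNA(depths)) stop("depths must not contain NA", call. = FALSE)
  if (!identical(species, "pH") && any(concentrations < 0, na.rm = TRUE)) {
    warning("negative concentrations floored to 0 (core ", core_id, ", ",
            species, ")", call. = FALSE)
    concentrations <- pmax(concentrations, 0)
  }
  structure(
    list(depths = depths, concentrations = concentrations,
         species = species, core_id = core_id, campaign = campaign,
         detection_limit = detection_limit),
    class = "depth_profile"
  )
}

#' @export
print.depth_profile <- function(x, ...) {
  cat(sprintf("Depth profile: %s, core %s%s, %d points, %.1f-%.1f mm\n",
              x$species, x$core_id,
              if (is.na(x$campaign)) "" else paste0(" (", x$campaign, ")"),
              length(x$depths), 1000 * min(x$depths), 1000 * max(x$depths)))
  invisible(x)
}

# Closed-form OLS of y on x. Returns slope, intercept, slope SE, r2, n.
# r2 is 0 by convention when y has no variance; SE is NA for n = 2.
.ols <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  if (sxx == 0) stop("degenerate window: all depths equal", call. = FALSE)
  sxy <- sum((x - mx) * (y - my))
  slope <- sxy / sxx
  intercept <- my - slope * mx
  resid <- y - intercept - slope * x
  ss_res <- sum(resid^2)
  ss_tot <- sum((y - my)^2)
  r2 <- if (ss_tot == 0) 0 else 1 - ss_res / ss_tot
  se <- if (n > 2) sqrt(ss_res / (n - 2) / sxx) else NA_real_
  list(slope = slope, intercept = intercept, se = se, r_squared = r2, n = n)
}

#' Fit a linear concentration gradient
#'
#' Ordinary least squares of concentration on depth over the points whose
#' depth lies in the half-open window `[top, bottom)`.
#'
#' @param profile A [depth_profile()].
#' @param window Numeric length-2, `c(top, bottom)` in m.
#' @return List with `slope` (mmol m-3 per m), `se` (NA for exactly 2
#'   points), `r_squared` (0 by convention for a constant profile), `n`,
#'   and the `window` used.
#' @export
fit_gradient <- function(profile, window) {
  stopifnot(inherits(profile, "depth_profile"),
            is.numeric(window), length(window) == 2, window[1] < window[2])
  sel <- profile$depths >= window[1] & profile$depths < window[2]
  if (sum(sel) < 2) {
    stop(sprintf("insufficient data: %d point(s) in window [%g, %g)",
                 sum(sel), window[1], window[2]), call. = FALSE)
  }
  fit <- .ols(profile$depths[sel], profile$concentrations[sel])
  c(fit[c("slope", "se", "r_squared", "n")], list(window = window))
}

# Default gradient window: the n_points profile points at/just below the SWI.
.swi_window_idx <- function(profile, n_points) {
  idx <- which(profile$depths >= 0)
  if (length(idx) < 2) {
    stop("fewer than 2 points below the SWI", call. = FALSE)
  }
  idx[seq_len(min(n_points, length(idx)))]
}

# Flux from a fitted slope and sediment properties (shared by the
# window-based and index-based paths).
.flux_from_fit <- function(fit, profile, props, window, registry, as_species) {
  phi <- mean(props$porosity)
  th2 <- tortuosity_squared(phi)
  d0 <- diffusion_coefficient(profile$species, props$temperature,
                              props$salinity, registry = registry,
                              as_species = as_species)
  flux <- -phi * (as.numeric(d0) / th2) * fit$slope
  structure(
    list(flux = flux, window = window, slope = fit$slope,
         slope_se = fit$se, r_squared = fit$r_squared, n = fit$n,
         species = profile$species,
         species_resolved = attr(d0, "species"),
         D0 = as.numeric(d0), porosity = phi, theta_squared = th2,
         core_id = profile$core_id, campaign = profile$campaign,
         convention = "positive downward; negative = efflux toward SWI"),
    class = "flux_result"
  )
}

#' @export
print.flux_result <- function(x, ...) {
  cat(sprintf(
    "Diffusive flux: %s (as %s), core %s\n  J = %.4g mmol m-2 d-1 (%s)\n",
    x$species, x$species_resolved, x$core_id, x$flux, x$convention))
  cat(sprintf(
    "  window [%.1f, %.1f] mm, slope %.4g +/- %s mmol m-4, r2 %.3f, n %d\n",
    1000 * x$window[1], 1000 * x$window[2], x$slope,
    if (is.na(x$slope_se)) "NA" else sprintf("%.3g", x$slope_se),
    x$r_squared, x$n))
  cat(sprintf("  D0 %.4g m2 d-1, phi %.3f, theta2 %.4f\n",
              x$D0, x$porosity, x$theta_squared))
  invisible(x)
}

#' Fickian diffusive flux from a pore-water profile
#'
#' J = -phi (D0(S,T)/theta^2) dC/dx, with the gradient from an OLS fit over
#' a depth window. By default the window is the `n_points` points adjacent
#' to the SWI (depth >= 0).
#'
#' @param profile A [depth_profile()].
#' @param props A [sediment_properties()].
#' @param window Optional `c(top, bottom)` in m (half-open). When NULL, the
#'   first `n_points` sediment points are used.
#' @param n_points Number of points in the default SWI window (default 4).
#' @param registry,as_species Passed to [diffusion_coefficient()].
#' @return A `flux_result`: signed flux (mmol m-2 d-1, positive downward)
#'   plus full provenance (window, slope and SE, r2, D0, phi, theta2).
#' @export
diffusive_flux <- function(profile, props, window = NULL, n_points = 4,
                           registry = NULL,
                           as_species = getOption(
                             "benthicflux.as_species", "HAsO4")) {
  stopifnot(inherits(profile, "depth_profile"),
            inherits(props, "sediment_properties"))
  if (is.null(window)) {
    idx <- .swi_window_idx(profile, n_points)
    fit <- .ols(profile$depths[idx], profile$concentrations[idx])
    window <- range(profile$depths[idx])
  } else {
    g <- fit_gradient(profile, window)
    fit <- list(slope = g$slope, se = g$se, r_squared = g$r_squared, n = g$n)
  }
  .flux_from_fit(fit, profile, props, window, registry, as_species)
}

#' Production rate and partitioning at a subsurface concentration maximum
#'
#' Estimates the net production feeding a subsurface peak as the sum of the
#' magnitudes of the diffusive fluxes fitted immediately above and below the
#' maximum, and partitions it into the fraction diffusing upward (toward the
#' SWI) and downward. Ties at the maximum are broken toward greater depth.
#'
#' @param profile A [depth_profile()] with an interior maximum.
#' @param props A [sediment_properties()].
#' @param peak_window_size Points per one-sided fit window, including the
#'   peak point (default 4).
#' @param registry,as_species Passed to [diffusion_coefficient()].
#' @return List with `production` (mmol m-2 d-1), `upward_fraction`,
#'   `downward_fraction`, `peak_depth` (m), and the two `flux_result`s
#'   (`flux_above`, `flux_below`).
#' @export
peak_partition <- function(profile, props, peak_window_size = 4,
                           registry = NULL,
                           as_species = getOption(
                             "benthicflux.as_species", "HAsO4")) {
  stopifnot(inherits(profile, "depth_profile"))
  conc <- profile$concentrations
  n <- length(conc)
  i <- max(which(conc == max(conc)))   # ties -> deepest
  if (i == 1 || i == n) {
    stop("no interior peak: profile maximum lies at the boundary",
         call. = FALSE)
  }
  k <- max(2, peak_window_size)
  above <- seq(max(1, i - k + 1), i)
  below <- seq(i, min(n, i + k - 1))
  fit_a <- .ols(profile$depths[above], conc[above])
  fit_b <- .ols(profile$depths[below], conc[below])
  fa <- .flux_from_fit(fit_a, profile, props,
                       range(profile$depths[above]), registry, as_species)
  fb <- .flux_from_fit(fit_b, profile, props,
                       range(profile$depths[below]), registry, as_species)
  production <- abs(fa$flux) + abs(fb$flux)
  upward <- if (production == 0) NA_real_ else abs(fa$flux) / production
  list(production = production,
       upward_fraction = upward,
       downward_fraction = if (is.na(upward)) NA_real_ else 1 - upward,
       peak_depth = profile$depths[i],
       flux_above = fa, flux_below = fb)
}

# First depth where the profile crosses `level` in the stated direction,
# linearly interpolated between bracketing samples. NA if never crossed.
.first_crossing <- function(depths, conc, level, direction = c("below",
                                                               "above")) {
  direction <- match.arg(direction)
  hit <- if (direction == "below") conc < level else conc > level
  j <- which(hit)[1]
  if (is.na(j)) return(NA_real_)
  if (j == 1) return(depths[1])
  c0 <- conc[j - 1]; c1 <- conc[j]
  if (c1 == c0) return(depths[j])
  depths[j - 1] + (level - c0) / (c1 - c0) * (depths[j] - depths[j - 1])
}

#' Geochemical features of a microsensor profile set
#'
#' Extracts the oxygen penetration depth (OPD: shallowest depth where O2
#' falls below the detection limit), the sulfide appearance depth (SAD:
#' shallowest depth where free sulfide exceeds it), the suboxic-zone
#' thickness (SAD - OPD), and the pH extrema with their depths. Crossings
#' are linearly interpolated between bracketing samples. A feature whose
#' crossing is not bracketed within its profile is reported as NA
#' (undefined beyond the profile), not an error.
#'
#' @param o2,h2s,ph [depth_profile()]s (any may be NULL, yielding NA for
#'   the corresponding features). Non-NULL profiles must have overlapping
#'   depth ranges.
#' @param detection_limit mmol m-3 (default 1, a typical microsensor limit).
#' @return An object of class `profile_features` with fields `opd`, `sad`,
#'   `suboxic_thickness` (m), `ph_max`, `ph_max_depth`, `ph_min`,
#'   `ph_min_depth`, and `detection_limit`.
#' @export
extract_features <- function(o2, h2s, ph, detection_limit = 1) {
  stopifnot(detection_limit > 0)
  profs <- Filter(Negate(is.null), list(o2 = o2, h2s = h2s, ph = ph))
  if (length(profs) == 0) stop("no profiles supplied", call. = FALSE)
  for (p in profs) stopifnot(inherits(p, "depth_profile"))
  tops <- vapply(profs, function(p) min(p$depths), numeric(1))
  bots <- vapply(profs, function(p) max(p$depths), numeric(1))
  if (max(tops) >= min(bots)) {
    stop("profile depth ranges do not overlap; cannot align features",
         call. = FALSE)
  }
  opd <- if (is.null(o2)) NA_real_ else
    .first_crossing(o2$depths, o2$concentrations, detection_limit, "below")
  sad <- if (is.null(h2s)) NA_real_ else
    .first_crossing(h2s$depths, h2s$concentrations, detection_limit, "above")
  if (!is.na(opd) && !is.na(sad) && sad < opd) {
    warning("SAD shallower than OPD; check detection limits", call. = FALSE)
  }
  ph_max <- ph_min <- ph_max_d <- ph_min_d <- NA_real_
  if (!is.null(ph)) {
    imax <- which.max(ph$concentrations)
    imin <- which.min(ph$concentrations)
    ph_max <- ph$concentrations[imax]; ph_max_d <- ph$depths[imax]
    ph_min <- ph$concentrations[imin]; ph_min_d <- ph$depths[imin]
  }
  structure(
    list(opd = opd, sad = sad,
         suboxic_thickness = if (is.na(opd) || is.na(sad)) NA_real_
                             else sad - opd,
         ph_max = ph_max, ph_max_depth = ph_max_d,
         ph_min = ph_min, ph_min_depth = ph_min_d,
         detection_limit = detection_limit),
    class = "profile_features"
  )
}

#' @export
print.profile_features <- function(x, ...) {
  mm <- function(v) if (is.na(v)) "undefined" else sprintf("%.2f mm", 1000 * v)
  cat("Microsensor profile features\n")
  cat(sprintf("  OPD:     %s\n", mm(x$opd)))
  cat(sprintf("  SAD:     %s\n", mm(x$sad)))
  cat(sprintf("  suboxic: %s\n", mm(x$suboxic_thickness)))
  if (!is.na(x$ph_max)) {
    cat(sprintf("  pH max:  %.2f at %s\n", x$ph_max, mm(x$ph_max_depth)))
    cat(sprintf("  pH min:  %.2f at %s\n", x$ph_min, mm(x$ph_min_depth)))
  }
  invisible(x)
}
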