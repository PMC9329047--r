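# Solid-phase inventory integration: INV = integral of (1 - phi) rho_s
# C_solid over a depth interval, discretized by the sectioning scheme.

#' Solid-phase concentration profile
#'
#' Declares either contiguous slices (`depth_top`/`depth_bot`, the default
#' sectioning geometry) or slice midpoints (`depths`), in m below the SWI.
#'
#' @param conc Solid-phase concentration per slice, micromoles per g dry
#'   weight.
#' @param depth_top,depth_bot Slice boundaries in m (boundaries mode).
#' @param depths Slice midpoints in m (midpoints mode; trapezoid
#'   integration is used).
#' @param species Element name (e.g. `"Fe"`, `"As"`).
#' @param extraction Extraction label (`"ascorbate"` or `"HCl"`).
#' @param core_id,campaign Identifiers.
#' @return An object of class `solid_phase_profile`.
#' @export
solid_phase_profile <- function(conc, depth_top = NULL, depth_bot = NULL,
                                depths = NULL, species = "Fe",
                                extraction = "ascorbate",
                                core_id = "core1",
                                campaign = NA_character_) {
  stopifnot(is.numeric(conc))
  if (any(conc < 0)) stop("concentrations must be >= 0", call. = FALSE)
  if (!is.null(depths)) {
    if (length(depths) != length(conc) || any(diff(depths) <= 0)) {
      stop("midpoints must be strictly increasing and match conc",
           call. = FALSE)
    }
    geometry <- "midpoints"
    depth_top <- depth_bot <- NULL
  } else {
    if (is.null(depth_top) || is.null(depth_bot) ||
        length(depth_top) != length(conc) ||
        length(depth_bot) != length(conc)) {
      stop("provide depth_top and depth_bot (or midpoints via depths)",
           call. = FALSE)
    }
    if (any(depth_bot <= depth_top) || any(diff(depth_top) <= 0)) {
      stop("slice boundaries must be increasing with depth_bot > depth_top",
         call. = FALSE)
    }
    geometry <- "boundaries"
  }
  structure(
    list(conc = conc, depth_top = depth_top, depth_bot = depth_bot,
         depths = depths, geometry = geometry, species = species,
         extraction = extraction, core_id = core_id, campaign = campaign),
    class = "solid_phase_profile"
  )
}

#' @export
print.solid_phase_profile <- function(x, ...) {
  rng <- if (x$geometry == "boundaries") {
    c(min(x$depth_top), max(x$depth_bot))
  } else {
    range(x$depths)
  }
  cat(sprintf(
    "Solid-phase profile: %s (%s), core %s, %d slices (%s), %.1f-%.1f cm\n",
    x$species, x$extraction, x$core_id, length(x$conc), x$geometry,
    100 * rng[1], 100 * rng[2]))
  invisible(x)
}

.solid_coverage <- function(profile) {
  if (profile$geometry == "boundaries") {
    c(min(profile$depth_top), max(profile$depth_bot))
  } else {
    range(profile$depths)
  }
}

#' Solid-phase inventory over a depth interval
#'
#' INV = sum over slices of (1 - phi) rho_s C_solid dz, with depth-averaged
#' porosity. Boundary-declared slices are clipped to the interval
#' (rectangle rule); midpoint-declared profiles use the trapezoid rule with
#' linear interpolation at the interval ends.
#'
#' @param profile A [solid_phase_profile()] (conc in micromol per g dry wt).
#' @param props A [sediment_properties()]; `solid_density` in g cm-3.
#' @param x_up,x_down Integration bounds in m, within profile coverage.
#' @return Inventory in mmol m-2.
#' @export
solid_inventory <- function(profile, props, x_up, x_down) {
  stopifnot(inherits(profile, "solid_phase_profile"),
            inherits(props, "sediment_properties"))
  if (x_up >= x_down) stop("need x_up < x_down", call. = FALSE)
  cov <- .solid_coverage(profile)
  if (x_up < cov[1] - 1e-12 || x_down > cov[2] + 1e-12) {
    stop(sprintf(
      "interval [%g, %g] m outside profile coverage [%g, %g] m",
      x_up, x_down, cov[1], cov[2]), call. = FALSE)
  }
  phi <- mean(props$porosity)
  rho_g_m3 <- props$solid_density * 1e6          # g cm-3 -> g m-3
  conc_mmol_g <- profile$conc * 1e-3             # umol g-1 -> mmol g-1
  if (profile$geometry == "boundaries") {
    lo <- pmax(profile$depth_top, x_up)
    hi <- pmin(profile$depth_bot, x_down)
    dz <- pmax(hi - lo, 0)
    sum((1 - phi) * rho_g_m3 * conc_mmol_g * dz)
  } else {
    xs <- seq(x_up, x_down, length.out = 257)
    cs <- stats::approx(profile$depths, conc_mmol_g, xout = xs,
                        rule = 2)$y
    dz <- diff(xs)
    sum((1 - phi) * rho_g_m3 * (cs[-1] + cs[-length(cs)]) / 2 * dz)
  }
}

#' Change in solid-phase inventory between two profiles
#'
#' `solid_inventory(before) - solid_inventory(after)`; positive values mean
#' a loss from the sediment over the interval.
#'
#' @param before,after [solid_phase_profile()]s covering the interval.
#' @param props A [sediment_properties()].
#' @param x_up,x_down Integration bounds in m.
#' @return Inventory change in mmol m-2 (positive = loss).
#' @export
inventory_change <- function(before, after, props, x_up, x_down) {
  solid_inventory(before, props, x_up, x_down) -
    solid_inventory(after, props, x_up, x_down)
}
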