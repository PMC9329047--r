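# Derived budgets: oxic-zone trapping and escape, mixed-layer dilution,
# sorption-capacity release, and element ratios of cumulative fluxes.

#' Escape flux past an oxic-zone trap
#'
#' Of a subsurface production rate, `upward_fraction` diffuses toward the
#' SWI; an oxic surface layer traps `trapped` of that, and the remainder can
#' escape to the water column. If the trap exceeds the upward flux the
#' escape is 0 and the result is flagged (`attr(x, "over_trapped")`).
#'
#' @param production Production rate (any flux unit; result is in the same
#'   unit).
#' @param upward_fraction Fraction of the production diffusing upward
#'   (0..1).
#' @param trapped Flux intercepted in the oxic layer, same unit as
#'   `production`.
#' @return Escape flux (same unit), with attributes `upward` and
#'   `over_trapped`.
#' @examples
#' escape_flux(0.85, 0.45, 0.3)  # ~0.08 umol m-2 d-1
#' @export
escape_flux <- function(production, upward_fraction, trapped) {
  if (production < 0 || trapped < 0 ||
      upward_fraction < 0 || upward_fraction > 1) {
    stop("inputs must be non-negative with upward_fraction in [0, 1]",
         call. = FALSE)
  }
  upward <- production * upward_fraction
  over <- trapped > upward
  escape <- if (over) 0 else upward - trapped
  structure(escape, upward = upward, over_trapped = over)
}

#' Water-column concentration from a diluted benthic release
#'
#' Dilutes a cumulative areal flux over the height of the mixed bottom
#' layer: mmol m-2 over h m gives mmol m-3 (micromolar), reported in
#' nanomolar.
#'
#' @param cumulative_flux Cumulative flux in mmol m-2.
#' @param height Mixed-layer height in m (> 0).
#' @return Concentration in nM.
#' @examples
#' mixed_layer_concentration(0.06, 15)  # 4 nM
#' @export
mixed_layer_concentration <- function(cumulative_flux, height) {
  if (any(height <= 0)) stop("height must be positive", call. = FALSE)
  cumulative_flux / height * 1000
}

#' Pore-water release from a loss of sorption capacity
#'
#' If the sediment loses a fraction of its capacity to adsorb a solute, the
#' desorbed mass (per unit bulk volume) dissolves into the pore water:
#' dC = fraction * adsorbed * (1 - phi) * rho_s / phi, converted to
#' micromoles per litre of pore water (micromolar).
#'
#' @param adsorbed_conc Adsorbed concentration, micromol per g dry weight.
#' @param capacity_loss_fraction Fraction of sorption capacity lost (0..1).
#' @param props A [sediment_properties()] (porosity, solid_density).
#' @return Pore-water concentration increase in micromolar.
#' @examples
#' props <- sediment_properties(0.85, solid_density = 2.6)
#' sorption_release(0.05, 0.10, props)  # > 1 uM
#' @export
sorption_release <- function(adsorbed_conc, capacity_loss_fraction, props) {
  stopifnot(inherits(props, "sediment_properties"))
  if (capacity_loss_fraction < 0 || capacity_loss_fraction > 1) {
    stop("capacity_loss_fraction must lie in [0, 1]", call. = FALSE)
  }
  phi <- mean(props$porosity)
  rho_g_m3 <- props$solid_density * 1e6
  umol_per_m3 <- capacity_loss_fraction * adsorbed_conc *
    (1 - phi) * rho_g_m3 / phi
  umol_per_m3 / 1000   # umol m-3 pore water -> umol L-1 (uM)
}

#' Element ratio of cumulative fluxes
#'
#' Ratio of two elements' cumulative fluxes across replicate cores, either
#' as the ratio of sums (mass-weighted, the default) or as the mean of
#' per-core ratios. The method is recorded on the result because the two
#' can differ substantially for skewed replicates.
#'
#' @param cumulative_a,cumulative_b Per-core cumulative fluxes (equal
#'   lengths; `cumulative_b` must be positive).
#' @param method `"ratio_of_sums"` or `"per_core_mean"`.
#' @return Dimensionless ratio with attribute `method`.
#' @export
element_ratio <- function(cumulative_a, cumulative_b,
                          method = c("ratio_of_sums", "per_core_mean")) {
  method <- match.arg(method)
  if (length(cumulative_a) != length(cumulative_b)) {
    stop("per-core vectors must have equal length", call. = FALSE)
  }
  if (any(cumulative_b <= 0)) {
    stop("denominator fluxes must be positive", call. = FALSE)
  }
  r <- switch(method,
              ratio_of_sums = sum(cumulative_a) / sum(cumulative_b),
              per_core_mean = mean(cumulative_a / cumulative_b))
  structure(r, method = method)
}

#' Compare a water-column concentration to a toxicity guideline
#'
#' @param conc_nM Concentration in nM.
#' @param guideline_nM Guideline value in nM (default 920, the US EPA acute
#'   marine guideline for arsenite).
#' @return List with `fraction_of_guideline` and logical `exceeds`.
#' @export
toxicity_check <- function(conc_nM, guideline_nM = 920) {
  if (guideline_nM <= 0) stop("guideline must be positive", call. = FALSE)
  list(fraction_of_guideline = conc_nM / guideline_nM,
       exceeds = conc_nM > guideline_nM)
}
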