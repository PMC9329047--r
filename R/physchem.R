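# Physical-chemistry primitives: free-solution diffusivities, tortuosity,
# porosity from water content, unit conversions.

# 1 cm2 s-1 = 1e-4 m2 * 86400 s d-1 = 8.64 m2 d-1
CM2S_TO_M2D <- 8.64

#' Sediment physical properties
#'
#' Container for the bulk properties that control every unit-bearing
#' conversion in the package: porosity (volume fraction of pore water),
#' solid-phase density, and the salinity and temperature of the pore water.
#'
#' @param porosity Volume fraction of pore water, strictly between 0 and 1.
#'   May be a vector (per depth); most consumers use the depth average.
#' @param solid_density Density of the solid phase in g cm-3. Default 2.6,
#'   a typical value for organic-rich coastal mud.
#' @param salinity Practical salinity (dimensionless), >= 0.
#' @param temperature Temperature in degrees Celsius, within -2..40.
#'
#' @return An object of class `sediment_properties`.
#' @examples
#' sediment_properties(porosity = 0.85, salinity = 30, temperature = 4)
#' @export
sediment_properties <- function(porosity, solid_density = 2.6,
                                salinity = 30, temperature = 4) {
  stopifnot(is.numeric(porosity), length(porosity) >= 1)
  if (any(porosity <= 0) || any(porosity >= 1)) {
    stop("porosity must lie strictly between 0 and 1", call. = FALSE)
  }
  if (!is.numeric(solid_density) || solid_density <= 1) {
    stop("solid_density must be > 1 g cm-3", call. = FALSE)
  }
  if (!is.numeric(salinity) || salinity < 0) {
    stop("salinity must be >= 0", call. = FALSE)
  }
  if (!is.numeric(temperature) || temperature < -2 || temperature > 40) {
    stop("temperature must be within -2..40 degC", call. = FALSE)
  }
  structure(
    list(porosity = porosity, solid_density = solid_density,
         salinity = salinity, temperature = temperature),
    class = "sediment_properties"
  )
}

#' @export
print.sediment_properties <- function(x, ...) {
  cat("Sediment properties\n")
  cat(sprintf("  porosity:      %s\n",
              paste(format(x$porosity, digits = 4), collapse = ", ")))
  cat(sprintf("  solid density: %.3g g cm-3\n", x$solid_density))
  cat(sprintf("  salinity:      %.4g\n", x$salinity))
  cat(sprintf("  temperature:   %.4g degC\n", x$temperature))
  invisible(x)
}

#' Load a diffusivity registry
#'
#' The registry maps species names to the intercept `m0` and slope `m1` of a
#' linear-in-temperature free-solution diffusivity relation,
#' D0 = (m0 + m1 T) 1e-6 cm2 s-1 (T in degC). The shipped file carries the
#' linear compilations commonly used in early-diagenesis work (Boudreau-style
#' ion fits; phosphate-analog fits for the arsenate oxyanions; linearized
#' estimates for the neutral species). It is plain CSV so users can override
#' any entry.
#'
#' @param path Path to a CSV file with columns `species`, `m0`, `m1`, `note`.
#'   Defaults to the registry shipped with the package.
#' @return A data.frame with class `diffusivity_registry`.
#' @export
diffusivity_registry <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "diffusivity_registry.csv",
                        package = "benthicflux", mustWork = TRUE)
  }
  reg <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("species", "m0", "m1")
  missing <- setdiff(required, names(reg))
  if (length(missing) > 0) {
    stop("diffusivity registry is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(reg$m0 <= 0)) {
    stop("registry intercepts m0 must be positive", call. = FALSE)
  }
  class(reg) <- c("diffusivity_registry", "data.frame")
  reg
}

# Species aliases used by readers and the scenario generator. Dissolved
# arsenic is mapped to a configurable oxyanion because the field data do not
# constrain the As species; override with options(benthicflux.as_species=).
resolve_species <- function(species, as_species = getOption(
                              "benthicflux.as_species", "HAsO4")) {
  stopifnot(length(species) == 1)
  aliases <- c(dFe = "Fe2+", Fe = "Fe2+", dMn = "Mn2+",
               dAs = as_species, As = as_species,
               SumH2S = "HS-", sumH2S = "HS-", HS = "HS-")
  if (species %in% names(aliases)) unname(aliases[[species]]) else species
}

#' Dynamic viscosity of seawater
#'
#' Kukulka et al. (1987) polynomial for the dynamic viscosity of seawater
#' (the correlation used by the standard seawater-property compilations),
#' in centipoise.
#'
#' @param temperature degC.
#' @param salinity Practical salinity.
#' @param pressure Pressure in bar (default 1.013253, surface).
#' @return Dynamic viscosity in centipoise.
#' @export
seawater_viscosity <- function(temperature, salinity = 35,
                               pressure = 1.013253) {
  t <- temperature; S <- salinity; P <- pressure
  1.7910 - t * (6.144e-02 - t * (1.4510e-03 - t * 1.6826e-05)) -
    1.5290e-04 * P + 8.3885e-08 * P^2 + 2.4727e-03 * S +
    t * (6.0574e-06 * P - 2.6760e-09 * P^2) +
    S * t * (4.8429e-05 - t * (4.7172e-06 - t * 7.5986e-08))
}

#' Free-solution diffusion coefficient
#'
#' Evaluates the registry's linear-in-temperature relation for a species and
#' applies a Stokes-Einstein salinity correction (scaling by the ratio of
#' freshwater to seawater dynamic viscosity at the same temperature).
#'
#' @param species Species name or alias (`dFe`, `dAs`, `SumH2S`, ...).
#' @param temperature degC, within -2..40.
#' @param salinity Practical salinity, within 0..50.
#' @param registry A `diffusivity_registry`; the shipped one by default.
#' @param as_species Registry species to use for dissolved arsenic
#'   (`"HAsO4"`, `"H2AsO4"` or `"H3AsO3"`).
#' @return D0 in m2 d-1, with attributes `species` (resolved registry name),
#'   `D0_cm2_s` and `viscosity_ratio` recording provenance.
#' @examples
#' diffusion_coefficient("Fe2+", temperature = 4, salinity = 0)
#' @export
diffusion_coefficient <- function(species, temperature, salinity,
                                  registry = NULL,
                                  as_species = getOption(
                                    "benthicflux.as_species", "HAsO4")) {
  if (is.null(registry)) registry <- diffusivity_registry()
  if (temperature < -2 || temperature > 40) {
    stop("temperature out of range (-2..40 degC): ", temperature,
         call. = FALSE)
  }
  if (salinity < 0 || salinity > 50) {
    stop("salinity out of range (0..50): ", salinity, call. = FALSE)
  }
  key <- resolve_species(species, as_species = as_species)
  row <- match(key, registry$species)
  if (is.na(row)) {
    stop(sprintf("unknown species '%s' (resolved to '%s'); registry has: %s",
                 species, key, paste(registry$species, collapse = ", ")),
         call. = FALSE)
  }
  d0_cm2_s <- (registry$m0[row] + registry$m1[row] * temperature) * 1e-6
  if (d0_cm2_s <= 0) {
    stop("registry relation gives non-positive D0 at T = ", temperature,
         call. = FALSE)
  }
  visc_ratio <- seawater_viscosity(temperature, 0) /
    seawater_viscosity(temperature, salinity)
  d0 <- d0_cm2_s * CM2S_TO_M2D * visc_ratio
  structure(d0, species = key, D0_cm2_s = d0_cm2_s,
            viscosity_ratio = visc_ratio)
}

#' Tortuosity correction factor
#'
#' theta^2 = 1 - 2 ln(phi), the Boudreau tortuosity correction that converts
#' the free-solution diffusivity to the sediment diffusivity Ds = D0/theta^2.
#'
#' @param porosity Volume fraction, 0 < phi <= 1.
#' @return theta^2 (dimensionless, >= 1).
#' @examples
#' tortuosity_squared(0.85)
#' @export
tortuosity_squared <- function(porosity) {
  if (any(porosity <= 0) || any(porosity > 1)) {
    stop("porosity must lie in (0, 1]", call. = FALSE)
  }
  1 - 2 * log(porosity)
}

#' Porosity from water content
#'
#' Computes porosity from the mass of water evaporated on drying, correcting
#' for the salt dissolved in the pore water: the evaporated mass understates
#' the pore-water mass by the salt fraction, and the residual salt inflates
#' the dry (solid) mass.
#'
#' @param wet_mass Wet sediment mass (g).
#' @param dry_mass Mass after drying to constant weight (g).
#' @param solid_density g cm-3 (default 2.6).
#' @param pore_water_density g cm-3 (default 1.025).
#' @param salinity Practical salinity of the pore water; the mass salt
#'   fraction is taken as salinity/1000.
#' @return Porosity (volume fraction of pore water).
#' @examples
#' porosity_from_water_content(10, 5, solid_density = 2.6,
#'                             pore_water_density = 1.02, salinity = 0)
#' @export
porosity_from_water_content <- function(wet_mass, dry_mass,
                                        solid_density = 2.6,
                                        pore_water_density = 1.025,
                                        salinity = 0) {
  if (any(dry_mass <= 0) || any(wet_mass < dry_mass)) {
    stop("need wet_mass >= dry_mass > 0", call. = FALSE)
  }
  if (solid_density <= 0 || pore_water_density <= 0) {
    stop("densities must be positive", call. = FALSE)
  }
  s <- salinity / 1000
  m_water <- (wet_mass - dry_mass) / (1 - s)   # true pore-water mass
  m_solid <- dry_mass - s * m_water            # remove residual salt
  if (any(m_solid <= 0)) {
    stop("salt-corrected solid mass <= 0: wet/dry masses inconsistent with ",
         "stated salinity", call. = FALSE)
  }
  v_water <- m_water / pore_water_density
  v_solid <- m_solid / solid_density
  v_water / (v_water + v_solid)
}
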