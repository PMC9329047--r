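# Shared fixtures: canonical sediment properties and small profile builders.

std_props <- function(porosity = 0.85, salinity = 30, temperature = 4) {
  sediment_properties(porosity, solid_density = 2.6, salinity = salinity,
                      temperature = temperature)
}

# Exactly linear profile C = intercept + slope * depth on a regular grid.
linear_profile <- function(slope, intercept = 0, n = 10, dx = 5e-4,
                           species = "dFe") {
  x <- seq(0, by = dx, length.out = n)
  depth_profile(x, intercept + slope * x, species = species)
}

# Symmetric tent profile peaking at the middle point.
tent_profile <- function(n_side = 5, dx = 1e-3, peak = 100,
                         species = "dFe") {
  x <- seq(0, by = dx, length.out = 2 * n_side + 1)
  conc <- peak - abs(seq(-n_side, n_side)) * (peak / n_side) * 0.5
  depth_profile(x, conc, species = species)
}
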