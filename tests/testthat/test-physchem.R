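# Physical-chemistry primitives.

test_that("diffusion_coefficient follows the registry relation and the
           salinity/temperature monotonicities", {
  # intercept case: T = 0, S = 0 gives m0 * 1e-6 cm2 s-1 exactly
  reg <- diffusivity_registry()
  for (sp in reg$species) {
    d <- diffusion_coefficient(sp, 0, 0)
    expect_equal(attr(d, "D0_cm2_s"),
                 reg$m0[reg$species == sp] * 1e-6, tolerance = 1e-12)
  }
  # hand evaluation with the shipped Fe2+ constants (3.31, 0.15)
  d4 <- diffusion_coefficient("Fe2+", 4, 0)
  expect_equal(attr(d4, "D0_cm2_s"), 3.91e-6, tolerance = 1e-9)
  # unit conversion: 1 cm2 s-1 = 8.64 m2 d-1
  expect_equal(as.numeric(d4) / attr(d4, "D0_cm2_s"), 8.64,
               tolerance = 1e-12)
  # monotone increasing in T, decreasing in S
  expect_gt(as.numeric(diffusion_coefficient("Fe2+", 10, 0)),
            as.numeric(d4))
  expect_lt(as.numeric(diffusion_coefficient("Fe2+", 4, 30)),
            as.numeric(d4))
  # aliases resolve; the As default is the HAsO4 oxyanion
  expect_identical(attr(diffusion_coefficient("dFe", 4, 30), "species"),
                   "Fe2+")
  expect_identical(attr(diffusion_coefficient("dAs", 4, 30), "species"),
                   "HAsO4")
  expect_identical(
    attr(diffusion_coefficient("dAs", 4, 30, as_species = "H3AsO3"),
         "species"), "H3AsO3")
})

test_that("diffusion_coefficient rejects unknown species and bad ranges", {
  expect_error(diffusion_coefficient("unobtainium", 4, 30),
               "unknown species.*Fe2\\+")
  expect_error(diffusion_coefficient("Fe2+", 45, 30), "temperature")
  expect_error(diffusion_coefficient("Fe2+", 4, -1), "salinity")
})

test_that("seawater viscosity matches tabulated values", {
  # pure water: 0.890 cP at 25 C, 1.567 cP at 4 C
  expect_equal(seawater_viscosity(25, 0), 0.899, tolerance = 0.02)
  expect_equal(seawater_viscosity(4, 0), 1.567, tolerance = 0.01)
  # seawater at S = 35 is more viscous
  expect_gt(seawater_viscosity(25, 35), seawater_viscosity(25, 0))
})

test_that("tortuosity_squared has the closed form and its bounds", {
  expect_identical(tortuosity_squared(1), 1)
  expect_equal(tortuosity_squared(exp(-0.5)), 2, tolerance = 1e-12)
  expect_equal(tortuosity_squared(0.85), 1.32504, tolerance = 1e-5)
  expect_error(tortuosity_squared(0), "porosity")
  expect_error(tortuosity_squared(1.1), "porosity")
  # theta2 >= 1, strictly decreasing in phi, so Ds = D0/theta2 <= D0
  phis <- seq(0.05, 1, by = 0.05)
  th <- tortuosity_squared(phis)
  expect_true(all(th >= 1))
  expect_true(all(diff(th) < 0))
})

test_that("porosity_from_water_content handles salt and degenerate cases", {
  expect_equal(
    porosity_from_water_content(10, 5, solid_density = 2.6,
                                pore_water_density = 1.02, salinity = 0),
    (5 / 1.02) / ((5 / 1.02) + (5 / 2.6)), tolerance = 1e-12)
  expect_equal(porosity_from_water_content(5, 5), 0)
  # salt correction moves mass from solid to water
  expect_gt(porosity_from_water_content(10, 5, salinity = 30),
            porosity_from_water_content(10, 5, salinity = 0))
  expect_error(porosity_from_water_content(5, 10), "wet_mass")
  # s = 0 reduces to the two-phase volume identity for arbitrary masses
  set.seed(42)
  for (i in 1:25) {
    dry <- runif(1, 1, 20); wet <- dry + runif(1, 0, 20)
    rs <- runif(1, 2, 3); rw <- runif(1, 1, 1.05)
    vw <- (wet - dry) / rw; vs <- dry / rs
    expect_equal(porosity_from_water_content(wet, dry, rs, rw, 0),
                 vw / (vw + vs), tolerance = 1e-12)
  }
})

test_that("sediment_properties validates its invariants", {
  expect_error(sediment_properties(0), "porosity")
  expect_error(sediment_properties(1), "porosity")
  expect_error(sediment_properties(0.8, solid_density = 0.9),
               "solid_density")
  expect_error(sediment_properties(0.8, temperature = 60), "temperature")
  expect_s3_class(std_props(), "sediment_properties")
})
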