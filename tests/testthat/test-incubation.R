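# Closed-core incubation mass balance with water replacement.

test_that("start_inventory accounts for the replacement operation", {
  expect_equal(start_inventory(10, 0.4, 0.3, 0), 1.0)
  expect_equal(start_inventory(10, 0.4, 0), 0.4 * 10)     # no replacement
  expect_equal(start_inventory(10, 0.4, 0.4, 3), 0.4 * 3) # full replacement
  # replacement with identical water is a no-op
  expect_equal(start_inventory(10, 0.4, 0.25, 10), 0.4 * 10)
  expect_error(start_inventory(10, 0.4, 0.5, 0), "v_repl")
})

test_that("interval_flux reproduces the hand-worked weekly example", {
  s <- incubation_series(c(0, 7), c(10, 20), v_olw = 0.4, v_repl = 0.3,
                         conc_repl = 0)
  # (0.4*20 - 1) umol over 2.83e-3 m2 and 7 d = 0.3534 mmol m-2 d-1
  expect_equal(interval_flux(s, 1), 7e-3 / (28.3e-4 * 7),
               tolerance = 1e-12)
  # no change, no replacement => zero flux
  s0 <- incubation_series(c(0, 7), c(10, 10), v_olw = 0.4, v_repl = 0)
  expect_equal(interval_flux(s0, 1), 0)
  # uptake is reported negative and flagged, not clipped
  su <- incubation_series(c(0, 7), c(10, 2), v_olw = 0.4, v_repl = 0)
  fs <- interval_flux(su)
  expect_lt(fs$flux[1], 0)
  expect_true(fs$qc_negative[1])
})

test_that("cumulative_flux integrates interval fluxes", {
  s <- simulate_incubation(function(t) rep(0.5, length(t)),
                           seq(0, 70, by = 7))
  fs <- interval_flux(s$series)
  expect_equal(fs$flux, rep(0.5, 10), tolerance = 1e-9)
  expect_equal(cumulative_flux(fs), 35, tolerance = 1e-9)
  expect_equal(cumulative_flux(fs[0, ]), 0)
})

test_that("mass conservation holds for 200 random replacement schedules", {
  set.seed(99)
  for (i in 1:200) {
    n <- sample(4:12, 1)
    times <- cumsum(c(0, runif(n - 1, 2, 10)))
    frac <- runif(1, 0, 1)
    a <- runif(1, 0, 3); b <- runif(1, -0.01, 0.05)
    fn <- function(t) a * exp(-t / 40) + pmax(b * t, 0)
    sim <- simulate_incubation(fn, times, v_olw = runif(1, 0.2, 0.6),
                               replacement_fraction = frac,
                               conc_repl = runif(1, 0, 5),
                               initial_conc = runif(1, 0, 5))
    est <- cumulative_flux(interval_flux(sim$series)) * 28.3e-4
    expect_equal(est, sim$truth$total_released_mmol, tolerance = 1e-9)
  }
})

test_that("replicate_stats uses the n-1 denominator (and n does not
           reproduce the printed values)", {
  march <- replicate_stats(c(0.24, 0.20, 0.06))
  expect_equal(round(march$mean, 2), 0.17)
  expect_equal(round(march$sd, 2), 0.09)
  may <- replicate_stats(c(0.28, 0.48, 0.18))
  expect_equal(round(may$sd, 2), 0.15)
  # the population (n) denominator gives 0.08 / 0.12 instead
  sd_n <- function(x) sqrt(mean((x - mean(x))^2))
  expect_equal(round(sd_n(c(0.24, 0.20, 0.06)), 2), 0.08)
  expect_equal(round(sd_n(c(0.28, 0.48, 0.18)), 2), 0.12)
  expect_equal(replicate_stats(rep(0.3, 4))$sd, 0)
  expect_true(is.na(replicate_stats(5)$sd))
  expect_error(replicate_stats(numeric(0)), "no values")
})

test_that("detect_onset finds the first exceedance", {
  conc <- c(rep(0.2, 8), 5, 8, 12)
  s <- incubation_series(seq(0, 70, by = 7), conc, v_olw = 0.4,
                         v_repl = 0.3, species = "SumH2S")
  expect_equal(detect_onset(s), 56)
  s0 <- incubation_series(seq(0, 70, by = 7), rep(0.2, 11), v_olw = 0.4,
                          v_repl = 0.3)
  expect_true(is.na(detect_onset(s0)))
})

test_that("series validation catches ordering and volume errors", {
  expect_error(incubation_series(c(0, 7, 7), c(1, 2, 3), 0.4, 0.3),
               "strictly increasing")
  expect_error(incubation_series(c(0, 7), c(1, 2), 0.4, 0.5), "v_repl")
  expect_error(incubation_series(c(0, 7), c(1, -2), 0.4, 0.3), ">= 0")
})
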