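# Synthetic-data generation with known truth: steady-state pore-water and
# microsensor profiles for the three seasonal regimes of a seasonally
# hypoxic basin, solid-phase profiles, and incubation time series with
# prescribed true flux histories.
#
# The pore-water construction is deliberately simple: a solute produced at
# a plane splits into an upward flux (to a fixed SWI concentration) and a
# downward flux (consumed where the concentration reaches zero), giving a
# piecewise-linear steady state whose true fluxes are analytic. No reaction
# terms act between the planes, so estimator recovery is exact in the
# noiseless case.

# Evaluate expr with a temporarily seeded RNG, restoring global state.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Steady-state pore-water profile with known production and partitioning
#'
#' Builds the piecewise-linear steady-state concentration field of a solute
#' produced at a plane at `production_depth` with rate `production_rate`,
#' of which `upward_fraction` diffuses to the SWI (held at `swi_conc`) and
#' the remainder diffuses down to a consumption plane where the
#' concentration reaches zero. Slopes are set through phi D0/theta^2 so
#' that [diffusive_flux()] and [peak_partition()] recover the truth
#' exactly on the noiseless grid.
#'
#' @param production_rate True production rate, mmol m-2 d-1 (>= 0).
#' @param upward_fraction Fraction diffusing toward the SWI (0..1).
#' @param production_depth Depth of the production plane in m; snapped to
#'   the grid.
#' @param props A [sediment_properties()].
#' @param species Species name used for the diffusivity lookup.
#' @param grid_dx Grid spacing in m (default 5e-4, i.e. 0.5 mm).
#' @param grid_max Profile extent in m; defaults to cover the consumption
#'   plane with 20 % margin.
#' @param noise_cv Multiplicative Gaussian noise coefficient of variation
#'   (default 0).
#' @param seed RNG seed for the noise (NULL = use current RNG state).
#' @param swi_conc Concentration at the SWI, mmol m-3 (default 0).
#' @param registry,as_species Passed to [diffusion_coefficient()].
#' @return List with `profile` (a [depth_profile()]) and `truth` (the
#'   prescribed production rate, fractions, plane depths and peak
#'   concentration).
#' @export
make_steady_profile <- function(production_rate, upward_fraction,
                                production_depth, props,
                                species = "dFe", grid_dx = 5e-4,
                                grid_max = NULL, noise_cv = 0, seed = NULL,
                                swi_conc = 0, registry = NULL,
                                as_species = getOption(
                                  "benthicflux.as_species", "HAsO4")) {
  stopifnot(inherits(props, "sediment_properties"),
            production_rate >= 0, grid_dx > 0,
            upward_fraction >= 0, upward_fraction <= 1,
            production_depth > 0)
  phi <- mean(props$porosity)
  d0 <- as.numeric(diffusion_coefficient(species, props$temperature,
                                         props$salinity,
                                         registry = registry,
                                         as_species = as_species))
  phi_ds <- phi * d0 / tortuosity_squared(phi)
  x_p <- round(production_depth / grid_dx) * grid_dx
  if (x_p < 2 * grid_dx) {
    stop("infeasible geometry: production plane too close to the SWI for ",
         "this grid", call. = FALSE)
  }
  j_up <- production_rate * upward_fraction
  j_dn <- production_rate * (1 - upward_fraction)
  slope_up <- j_up / phi_ds
  peak_conc <- swi_conc + slope_up * x_p
  slope_dn <- j_dn / phi_ds
  x_c <- if (j_dn > 0) x_p + peak_conc / slope_dn else Inf
  if (is.null(grid_max)) {
    grid_max <- if (is.finite(x_c)) {
      ceiling(1.2 * x_c / grid_dx) * grid_dx
    } else {
      3 * x_p
    }
  }
  if (grid_max <= x_p) {
    stop("infeasible geometry: grid_max must exceed the production depth",
         call. = FALSE)
  }
  x <- seq(0, grid_max, by = grid_dx)
  conc <- ifelse(x <= x_p,
                 swi_conc + slope_up * x,
                 pmax(peak_conc - slope_dn * (x - x_p), 0))
  if (noise_cv > 0) {
    conc <- .with_seed(seed,
                       pmax(conc * (1 + noise_cv * stats::rnorm(length(conc))),
                            0))
  }
  list(
    profile = depth_profile(x, conc, species = species,
                            core_id = "synthetic", campaign = "synthetic"),
    truth = list(production_rate = production_rate,
                 upward_fraction = upward_fraction,
                 production_depth = x_p, consumption_depth = x_c,
                 peak_conc = peak_conc, phi_ds = phi_ds, species = species)
  )
}

# --- microsensor profile templates -------------------------------------

# O2 declining linearly from the bottom-water value so that it crosses the
# detection limit exactly at the prescribed OPD; floored at zero.
.o2_template <- function(bw_conc, opd, limit = 1, dx = 1e-4,
                         extent = 6e-3) {
  x <- seq(0, extent, by = dx)
  conc <- if (bw_conc <= limit) {
    rep(max(bw_conc, 0), length(x)) * pmax(1 - x / (2 * dx + extent), 0)
  } else {
    pmax(bw_conc - (bw_conc - limit) * x / opd, 0)
  }
  depth_profile(x, conc, species = "O2", core_id = "synthetic")
}

# Free sulfide rising linearly from zero so that it crosses the detection
# limit exactly at the prescribed SAD.
.h2s_template <- function(sad, deep_conc, limit = 1, dx = 5e-4,
                          extent = 6e-2) {
  x <- seq(0, extent, by = dx)
  slope <- (deep_conc - limit) / (extent - sad)
  x_s <- sad - limit / slope
  conc <- pmax(slope * (x - x_s), 0)
  depth_profile(x, conc, species = "SumH2S", core_id = "synthetic")
}

# pH as a baseline with two Gaussian excursions (alkaline and acidic).
.ph_template <- function(base, max_val, max_depth, min_val, min_depth,
                         dx = 5e-4, extent = 6e-2,
                         w_max = 2e-3, w_min = 6e-3) {
  x <- seq(0, extent, by = dx)
  snap <- function(d) round(d / dx) * dx
  md <- snap(max_depth); nd <- snap(min_depth)
  ph <- base +
    (max_val - base) * exp(-0.5 * ((x - md) / w_max)^2) +
    (min_val - base) * exp(-0.5 * ((x - nd) / w_min)^2)
  depth_profile(x, ph, species = "pH", core_id = "synthetic")
}

# --- scenario presets ---------------------------------------------------

#' Seasonal scenario presets
#'
#' Parameter sets for the three seasonal geochemical regimes of a
#' seasonally hypoxic basin: `"march"` (oxygenated bottom water, active
#' electrogenic sulfur oxidation: deep suboxic zone, alkaline surface /
#' acidic deep pH excursions, strong FeS-dissolution source of dFe and
#' dAs), `"may"` (bioturbation-driven iron cycling: shallow pH minimum at
#' the oxygen penetration depth, weaker dFe source, shallow dAs source),
#' and `"august"` (anoxic/euxinic: sulfide at the SWI, no dFe
#' accumulation, dAs peak sustained by sulfide-driven desorption).
#' Incubation flux histories follow the same regimes: immediate dFe
#' release decaying over weeks, delayed (march/may) or immediate (august)
#' sulfide breakthrough, and delayed-peak (march) or immediate (may) dAs
#' release.
#'
#' @return Named list of preset parameter lists.
#' @export
scenario_presets <- function() {
  list(
    march = list(
      salinity = 30, temperature = 4, porosity = 0.85,
      o2_bw = 329, opd = 1.4e-3, sad = 41e-3, h2s_deep = 1500,
      ph = list(base = 7.9, max_val = 8.82, max_depth = 1.4e-3,
                min_val = 6.4, min_depth = 41e-3),
      dfe = list(rate = 2.3, upward = 0.60, depth = 0.025),
      das = list(rate = 0.85e-3, upward = 0.45, depth = 0.020),
      solids = list(fe_surface = 150, fe_efold = 0.02, fe_bg = 30,
                    as_surface = 0.30, as_efold = 0.02, as_bg = 0.05),
      incubation = list(
        weeks = 23,
        dfe = function(t) 4 * exp(-t / 30),
        h2s = function(t) 5 / (1 + exp(-(t - 100) / 8)),
        das = function(t) (3e-3 * exp(1) / 50) * t * exp(-t / 50))
    ),
    may = list(
      salinity = 30, temperature = 10, porosity = 0.85,
      o2_bw = 175, opd = 1.0e-3, sad = 38e-3, h2s_deep = 1500,
      ph = list(base = 7.45, max_val = 7.7, max_depth = 20e-3,
                min_val = 7.10, min_depth = 1.0e-3),
      dfe = list(rate = 1.4, upward = 0.78, depth = 0.015),
      das = list(rate = 1.52e-3, upward = 0.50, depth = 0.0025),
      solids = list(fe_surface = 100, fe_efold = 0.03, fe_bg = 30,
                    as_surface = 0.30, as_efold = 0.03, as_bg = 0.05),
      incubation = list(
        weeks = 15,
        dfe = function(t) 2.5 * exp(-t / 20),
        h2s = function(t) 1 / (1 + exp(-(t - 55) / 5)),
        das = function(t) 17.5e-3 * exp(-t / 17))
    ),
    august = list(
      salinity = 30, temperature = 18, porosity = 0.85,
      o2_bw = 0.5, opd = NA_real_, sad = 0, h2s_deep = 3000,
      ph = list(base = 7.3, max_val = 7.9, max_depth = 0,
                min_val = 7.3, min_depth = 30e-3),
      dfe = NULL,
      das = list(peak_conc = 1.5, upward = 0.50, depth = 0.025),
      solids = list(fe_surface = 40, fe_efold = 0.03, fe_bg = 20,
                    as_surface = 0.12, as_efold = 0.03, as_bg = 0.05),
      incubation = list(
        weeks = 7,
        dfe = function(t) 0 * t,
        h2s = function(t) 5 * (1 - exp(-t / 10)),
        das = function(t) 0 * t)
    )
  )
}

.get_preset <- function(preset) {
  presets <- scenario_presets()
  if (!preset %in% names(presets)) {
    stop("unknown preset '", preset, "'; available: ",
         paste(names(presets), collapse = ", "), call. = FALSE)
  }
  presets[[preset]]
}

# Solid-phase slice profile with exponential depth decay; the standard
# sectioning scheme (0.5 cm slices to 6 cm, 1 cm slices to 12 cm).
.solids_template <- function(surface, efold, bg, species, scale = 1) {
  top <- c(seq(0, 0.055, by = 0.005), seq(0.06, 0.11, by = 0.01))
  bot <- c(seq(0.005, 0.06, by = 0.005), seq(0.07, 0.12, by = 0.01))
  mid <- (top + bot) / 2
  conc <- scale * (bg + (surface - bg) * exp(-mid / efold))
  solid_phase_profile(conc, depth_top = top, depth_bot = bot,
                      species = species, extraction = "ascorbate",
                      core_id = "synthetic")
}

#' Generate a full seasonal scenario with known truth
#'
#' Builds the microsensor profiles (O2, free sulfide, pH), the pore-water
#' dFe and dAs profiles, and solid-phase ascorbate-extractable Fe and As
#' profiles for one seasonal preset, together with the truth record the
#' estimators are validated against. Noise (if any) is applied to the
#' pore-water profiles; microsensor templates are returned exactly so that
#' feature extraction is testable to interpolation precision.
#'
#' @param preset `"march"`, `"may"` or `"august"`.
#' @param seed RNG seed (used only when `noise_cv > 0`).
#' @param noise_cv Multiplicative noise CV for the pore-water profiles.
#' @param grid_dx Pore-water grid spacing in m (default 5e-4).
#' @return List with `props`, `profiles` (named list `o2`, `h2s`, `ph`,
#'   `dfe`, `das`), `solids` (`fe_asc`, `as_asc`), and `truth` (features
#'   and production rates/fractions).
#' @export
make_scenario <- function(preset, seed = 1, noise_cv = 0, grid_dx = 5e-4) {
  p <- .get_preset(preset)
  props <- sediment_properties(p$porosity, salinity = p$salinity,
                               temperature = p$temperature)
  o2 <- .o2_template(p$o2_bw, p$opd)
  h2s <- .h2s_template(p$sad, p$h2s_deep)
  ph <- do.call(.ph_template, p$ph)

  dfe <- if (is.null(p$dfe)) NULL else {
    make_steady_profile(p$dfe$rate, p$dfe$upward, p$dfe$depth, props,
                        species = "dFe", grid_dx = grid_dx,
                        noise_cv = noise_cv, seed = seed)
  }
  das_par <- p$das
  if (!is.null(das_par$peak_conc)) {
    # derive the production rate from the prescribed peak concentration
    phi <- mean(props$porosity)
    d0 <- as.numeric(diffusion_coefficient("dAs", props$temperature,
                                           props$salinity))
    phi_ds <- phi * d0 / tortuosity_squared(phi)
    j_up <- phi_ds * das_par$peak_conc / das_par$depth
    das_par$rate <- j_up / das_par$upward
  }
  das <- make_steady_profile(das_par$rate, das_par$upward, das_par$depth,
                             props, species = "dAs", grid_dx = grid_dx,
                             noise_cv = noise_cv,
                             seed = if (is.null(seed)) NULL else seed + 1)

  truth <- list(
    preset = preset,
    opd = p$opd, sad = p$sad,
    suboxic_thickness = if (is.na(p$opd)) NA_real_ else p$sad - p$opd,
    ph_max = p$ph$max_val, ph_min = p$ph$min_val,
    dfe = if (is.null(dfe)) NULL else dfe$truth,
    das = das$truth
  )
  list(props = props,
       profiles = list(o2 = o2, h2s = h2s, ph = ph,
                       dfe = if (is.null(dfe)) NULL else dfe$profile,
                       das = das$profile),
       solids = list(
         fe_asc = .solids_template(p$solids$fe_surface, p$solids$fe_efold,
                                   p$solids$fe_bg, "Fe"),
         as_asc = .solids_template(p$solids$as_surface, p$solids$as_efold,
                                   p$solids$as_bg, "As")),
       truth = truth)
}

#' Simulate a closed-core incubation with water replacement
#'
#' Forward mass balance: between samplings the overlying-water inventory
#' grows by the time-integral of the prescribed true flux times core area;
#' at each sampling the concentration is recorded (optionally with
#' multiplicative noise) and then `replacement_fraction` of the water is
#' replaced. An exact ledger of the total released mass is kept, so
#' noiseless interval fluxes integrate to the ledger to machine precision.
#'
#' @param flux_fn True flux history, a function of time (d) returning
#'   mmol m-2 d-1; must be integrable on the schedule.
#' @param times Sampling times in days, strictly increasing, starting at
#'   the incubation start.
#' @param v_olw Overlying-water volume in L (default 0.42, ~15 cm over a
#'   28.3 cm2 core).
#' @param replacement_fraction Fraction of the overlying water replaced at
#'   every event (default 0.75).
#' @param conc_repl Replacement-water concentration, mmol m-3 (default 0).
#' @param initial_conc Overlying-water concentration at the first event,
#'   mmol m-3 (default 0).
#' @param core_area m2 (default 28.3 cm2).
#' @param noise_cv Multiplicative measurement noise CV (default 0).
#' @param seed RNG seed for the noise.
#' @param species,core_id Identifiers for the returned series.
#' @return List with `series` (an [incubation_series()]) and `truth`
#'   (per-interval released mass and mean flux, total released mass, and
#'   the true cumulative flux in mmol m-2).
#' @export
simulate_incubation <- function(flux_fn, times, v_olw = 0.42,
                                replacement_fraction = 0.75,
                                conc_repl = 0, initial_conc = 0,
                                core_area = 28.3e-4, noise_cv = 0,
                                seed = NULL, species = "solute",
                                core_id = "core1") {
  stopifnot(is.function(flux_fn), length(times) >= 2,
            all(diff(times) > 0),
            replacement_fraction >= 0, replacement_fraction <= 1)
  n <- length(times)
  v_repl <- replacement_fraction * v_olw
  v_m3 <- v_olw * 1e-3
  released <- numeric(n - 1)            # mmol per interval
  conc_true <- numeric(n)
  conc_true[1] <- initial_conc
  post <- (v_repl * conc_repl + (v_olw - v_repl) * conc_true[1]) / v_olw
  for (i in 2:n) {
    released[i - 1] <- core_area *
      stats::integrate(flux_fn, times[i - 1], times[i],
                       rel.tol = 1e-12, abs.tol = 1e-14,
                       subdivisions = 500L)$value
    conc_true[i] <- post + released[i - 1] / v_m3
    post <- (v_repl * conc_repl + (v_olw - v_repl) * conc_true[i]) / v_olw
  }
  measured <- if (noise_cv > 0) {
    .with_seed(seed,
               pmax(conc_true * (1 + noise_cv * stats::rnorm(n)), 0))
  } else {
    conc_true
  }
  dt <- diff(times)
  list(
    series = incubation_series(times, measured, v_olw = v_olw,
                               v_repl = v_repl, conc_repl = conc_repl,
                               species = species, core_id = core_id,
                               core_area = core_area),
    truth = list(released_mmol = released,
                 interval_mean_flux = released / (core_area * dt),
                 total_released_mmol = sum(released),
                 cumulative_mmol_m2 = sum(released) / core_area,
                 conc_true = conc_true)
  )
}

#' Simulate the replicate incubation experiment of a seasonal preset
#'
#' Runs [simulate_incubation()] for dFe, free sulfide and dAs with the
#' preset's true flux histories on a weekly schedule, for `n_cores`
#' replicate cores whose fluxes are scaled by a lognormal core factor
#' (emulating between-core heterogeneity).
#'
#' @param preset `"march"`, `"may"` or `"august"`.
#' @param seed RNG seed; drives the core factors and any measurement noise.
#' @param noise_cv Measurement noise CV (default 0).
#' @param n_cores Number of replicate cores (default 3).
#' @param core_sd Log-scale SD of the per-core flux scaling (default 0.35).
#' @return Nested list: `result[[species]][[core]]` is a
#'   [simulate_incubation()] result; also `schedule` and `core_factors`.
#' @export
make_incubation_scenario <- function(preset, seed = 1, noise_cv = 0,
                                     n_cores = 3, core_sd = 0.35) {
  p <- .get_preset(preset)
  times <- seq(0, p$incubation$weeks * 7, by = 7)
  factors <- .with_seed(seed, exp(stats::rnorm(n_cores, 0, core_sd)))
  fns <- list(dFe = p$incubation$dfe, SumH2S = p$incubation$h2s,
              dAs = p$incubation$das)
  out <- lapply(names(fns), function(sp) {
    lapply(seq_len(n_cores), function(k) {
      fn <- fns[[sp]]
      scaled <- function(t) factors[k] * fn(t)
      simulate_incubation(scaled, times, noise_cv = noise_cv,
                          seed = if (is.null(seed)) NULL
                                 else seed + 100 * k + match(sp, names(fns)),
                          species = sp, core_id = paste0("core", k))
    })
  })
  names(out) <- names(fns)
  c(out, list(schedule = times, core_factors = factors, preset = preset))
}
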