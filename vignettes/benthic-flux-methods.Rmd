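---
title: "Methods: benthic flux estimation from incubations and pore-water profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: benthic flux estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(benthicflux)
```

## Scope and conventions

benthicflux quantifies sediment–water solute exchange three ways —
closed-core incubation mass balance, Fickian pore-water gradients, and
solid-phase inventory change — and ties them together in simple budgets.
Canonical internal units are: depth in m (positive downward, SWI at 0),
concentration in mmol m⁻³ (numerically micromolar), flux in
mmol m⁻² d⁻¹ (positive downward, so an efflux toward the SWI is
negative), diffusivity in m² d⁻¹, solid-phase content in µmol g⁻¹ dry
weight, and inventories in mmol m⁻². All file I/O converts at the
boundary; gradient windows are half-open `[top, bottom)`.

## Incubation mass balance

Weekly sampling of a closed core removes and replaces ~75 % of the
overlying water, so the inventory at the start of each interval is the
mixture `V_repl [S]_repl + (V_olw − V_repl) [S]_{t−1}`; the interval flux
divides the inventory change by core area (default 28.3 cm², a 6 cm
liner) and the exact interval duration taken from the timestamps (skipped
weeks are allowed). Negative fluxes are physically meaningful
(re-adsorption, uptake) and are reported with a QC flag rather than
clipped. Replicate spread is summarized as mean ± sample SD with the
n−1 denominator — the only choice that reproduces the published
0.17 ± 0.09 / 0.32 ± 0.15 mmol m⁻² summaries, which the test suite
asserts as an inequality against the n denominator. Measured
concentrations are taken to be pre-replacement (the sampling protocol
draws the sample before the water change); the data model records them
as `conc_end`.

## Diffusive fluxes

`J = −φ (D₀/θ²) dC/dx` with `θ² = 1 − 2 ln φ`. The gradient is an OLS
slope over a declared window; the default window is the 4 points adjacent
to the feature of interest (the SWI, or either side of a subsurface
peak). That default is a reproducibility choice, not a claim about the
original continuous-profile fitting machinery, which is out of scope; all
windows are user-overridable and recorded in the result. The production
rate feeding a subsurface maximum is `|J_above| + |J_below|` on the two
one-sided windows that include the peak point; ties at the maximum break
toward greater depth, which is deterministic and matches the sub-peak
placement of the consumption zone.

D₀ comes from a plain-CSV registry of linear-in-temperature relations,
`D₀ = (m0 + m1·T)·10⁻⁶ cm² s⁻¹` (1 cm² s⁻¹ = 8.64 m² d⁻¹), with
Boudreau-style constants for the ions and documented analog/linearized
estimates where no ionic fit exists; users can point
`diffusivity_registry()` at their own file. Salinity enters through a
Stokes–Einstein scaling by the freshwater-to-seawater dynamic-viscosity
ratio (Kukulka et al. 1987 polynomial, surface pressure). The field data
do not constrain which dissolved-arsenic species dominates, so dAs maps
to HAsO₄²⁻ by default with `options(benthicflux.as_species =)` switching
to H₂AsO₄⁻ or H₃AsO₃; the resolved species is carried in every flux
result's provenance. Pressure dependence and speciation equilibria are
deliberately out of scope.

## Microsensor features

OPD is the shallowest depth where O₂ falls below the detection limit
(default 1 mmol m⁻³), SAD the shallowest depth where free sulfide
exceeds it, both linearly interpolated between bracketing samples —
microsensor grids are ≤0.5 mm, so higher-order interpolation adds
nothing testable. Features whose crossing is not bracketed are reported
as NA rather than raising, since "no sulfide anywhere" is a result, not
an error. If the first sample already sits past the threshold (anoxic
bottom water), the profile's top depth is returned.

## Solid-phase inventories

`INV = Σ (1−φ) ρ_s C_solid Δx` over the declared slices (rectangle rule,
clipped at the integration bounds), or the trapezoid rule when only slice
midpoints are declared. Defaults: ρ_s = 2.6 g cm⁻³ and a depth-averaged
porosity, both overridable. The distinction between ascorbate- and
HCl-extractable pools is metadata only.

## Synthetic scenarios: the stated world

The generator exists so that every estimator can be validated against an
analytic truth, and its defaults are the observed conditions of the three
seasonal regimes, not tuning knobs:

* **march** (oxic bottom water, e-SOx): O₂ 329 µM at the SWI, OPD
  1.4 mm, SAD 41 mm, pH maximum 8.82 near the OPD and minimum 6.4 near
  the SAD; dFe production 2.3 mmol m⁻² d⁻¹ with 60 % upward; dAs
  production 0.85 µmol m⁻² d⁻¹ with 45 % upward.
* **may** (bioturbation-driven iron cycling): O₂ 175 µM, OPD 1.0 mm,
  suboxic zone 37 mm, pH minimum 7.10 at the OPD recovering to 7.7 at
  depth; dFe 1.4 mmol m⁻² d⁻¹ with 78 % upward; dAs 1.52 µmol m⁻² d⁻¹.
  The upward fraction of the May dAs source is not reported; the preset
  uses 0.5 and the choice is not revisited.
* **august** (anoxia/euxinia): sulfide from the SWI (SAD ≈ 0), pH
  minimum 7.3, no dFe accumulation; the dAs profile is parameterized
  from its observed peak (1.5 µM at 2.5 cm), from which the implied
  production rate is derived rather than prescribed.

Pore-water profiles are piecewise-linear steady states of a plane source
splitting into an upward flux (to a zero-concentration SWI) and a
downward flux (to a consumption plane where the concentration reaches
zero, whose depth follows from the prescribed partitioning). No reaction
terms act between the planes — the observed profiles are smooth, not
kinked — so a green recovery test establishes estimator correctness, not
realism of profile shape. Noise, when requested, is multiplicative
Gaussian with a given CV, floored at zero, through one explicitly seeded
generator (identical seed ⇒ bit-identical output).

Incubation truth histories are shape choices anchored to the observed
magnitudes and timings: exponential decay for dFe (March max
4 mmol m⁻² d⁻¹, τ = 30 d; May max 2.5, τ = 20 d), a logistic sulfide
breakthrough (March centered at 100 d, May at 55 d, so detection falls in
the observed 50–100 d and 30–50 d windows; August rises immediately),
and a delayed-peak gamma shape for March dAs (maximum ~3 µmol m⁻² d⁻¹
near day 50) versus an immediate exponential for May dAs (initial
~17.5 µmol m⁻² d⁻¹). The simulator integrates these with adaptive
quadrature and keeps an exact ledger of released mass, so noiseless
interval fluxes integrate to the ledger to machine precision for any
replacement fraction or schedule — this conservation identity, checked
over 200 random schedules, is the incubation module's primary oracle.
Replicate cores are emulated by a lognormal per-core flux factor
(log-SD 0.35, reflecting the factor 2–4 spread of the published
replicate totals); real between-core structure (patchy fauna, wall
effects) is not modelled.

## Numerical choices and degenerate inputs

OLS slope SE is undefined (NA) for two-point windows; r² of a constant
profile is reported as 0 by convention. Because generator profiles are
piecewise linear, grid refinement cannot degrade recovery — the
refinement test asserts machine-level error at four resolutions rather
than a decreasing error curve, which would be vacuous here. Under 5 %
multiplicative noise the default 4-point windows are deliberately noisy
(they sit where concentrations, hence absolute noise, are largest);
recovery to ≤5 % median relative error uses wide one-sided windows
(`peak_window_size = 40`) that average the noise over each linear limb.
Profiles with negative concentrations are floored at zero with a
warning; unsorted input rows are sorted on load with a warning;
replacement volumes exceeding the overlying volume, non-monotone times
and out-of-range temperatures/salinities are errors.

## Budgets and their caveats

`escape_flux` is bookkeeping: upward flux minus oxic-zone trapping,
floored at zero with an over-trapping flag. The mixed-layer dilution
range uses only cores with detectable fluxes (March + May); the August
cores (0.004–0.007 mmol m⁻²) would imply ~0.3–0.5 nM, inconsistent with
the published 4 nM lower bound, so the default range excludes
cores flagged as having no detectable flux. `element_ratio` defaults to
the ratio of sums; the published As/Fe ratios (0.003, 0.014) came from a
regression of weekly fluxes whose underlying data are not printed, so
they are not reproduced here — the result always carries its method
label. `sorption_release` is a capacity-loss argument (a ~10 % loss of
the ~0.05 µmol g⁻¹ sulfide-free adsorbed pool yields >1 µM pore-water
dAs), not a sorption isotherm.

## Known limitations

No irrigation or bioturbation transport terms in the flux estimators; no
diffusive-boundary-layer correction for the incubations; pH profiles are
shape templates, not speciation calculations; the synthetic scenarios
validate estimators, not diagenetic mechanism. The acceptance surface
reproduces the published summary statistics exactly and substitutes
generator-truth recovery for the profile-derived rates, whose original
depth windows are recoverable only from figures.
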