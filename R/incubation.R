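# Benthic efflux estimation from sequentially sampled closed-core
# incubations with partial overlying-water replacement.
#
# Bookkeeping: at each sampling event the overlying water is measured
# (conc_end, pre-replacement), then a volume v_repl is removed and replaced
# with water of concentration conc_repl. The start inventory of the next
# interval therefore mixes replacement water with the water that remained.

#' Incubation time series for one core and one species
#'
#' @param time_d Sampling times in days, strictly increasing. The first
#'   event is the incubation start (its `conc_end` is the initial
#'   overlying-water concentration, measured before the first replacement).
#' @param conc_end Measured concentration at each event, mmol m-3,
#'   pre-replacement.
#' @param v_olw Overlying-water volume in L (scalar or per event).
#' @param v_repl Replaced volume in L at each event, 0 <= v_repl <= v_olw.
#' @param conc_repl Concentration of the replacement water, mmol m-3.
#' @param species,core_id Identifiers.
#' @param core_area Sediment surface area in m2 (default 28.3 cm2, a
#'   standard 6 cm inner-diameter core liner).
#' @return An object of class `incubation_series`.
#' @export
incubation_series <- function(time_d, conc_end, v_olw, v_repl,
                              conc_repl = 0, species = "solute",
                              core_id = "core1", core_area = 28.3e-4) {
  n <- length(time_d)
  stopifnot(n >= 1, length(conc_end) == n)
  v_olw <- rep_len(v_olw, n)
  v_repl <- rep_len(v_repl, n)
  conc_repl <- rep_len(conc_repl, n)
  if (any(diff(time_d) <= 0)) {
    stop("sampling times must be strictly increasing (core ", core_id, ")",
         call. = FALSE)
  }
  if (any(v_repl < 0) || any(v_repl > v_olw)) {
    stop("need 0 <= v_repl <= v_olw", call. = FALSE)
  }
  if (any(conc_end < 0) || any(conc_repl < 0)) {
    stop("concentrations must be >= 0", call. = FALSE)
  }
  if (core_area <= 0) stop("core_area must be positive", call. = FALSE)
  structure(
    list(time_d = time_d, conc_end = conc_end, v_olw = v_olw,
         v_repl = v_repl, conc_repl = conc_repl, species = species,
         core_id = core_id, core_area = core_area),
    class = "incubation_series"
  )
}

#' @export
print.incubation_series <- function(x, ...) {
  cat(sprintf(
    "Incubation series: %s, core %s, %d events over %.0f d, area %.3g m2\n",
    x$species, x$core_id, length(x$time_d), diff(range(x$time_d)),
    x$core_area))
  invisible(x)
}

#' Overlying-water inventory at the start of an interval
#'
#' After a replacement operation, the start inventory mixes the replacement
#' water with the overlying water that remained:
#' `v_repl * conc_repl + (v_olw - v_repl) * prev_conc`.
#'
#' @param prev_conc Concentration measured at the previous event, mmol m-3.
#' @param v_olw,v_repl Volumes in L.
#' @param conc_repl Replacement-water concentration, mmol m-3.
#' @return Inventory in micromoles (L times mmol m-3).
#' @export
start_inventory <- function(prev_conc, v_olw, v_repl, conc_repl = 0) {
  if (any(v_repl < 0) || any(v_repl > v_olw)) {
    stop("need 0 <= v_repl <= v_olw", call. = FALSE)
  }
  v_repl * conc_repl + (v_olw - v_repl) * prev_conc
}

#' Per-interval benthic fluxes from an incubation series
#'
#' For each interval the flux is the change in overlying-water inventory
#' (end minus replacement-corrected start) divided by core area and
#' interval duration. Negative fluxes (uptake by the sediment) are reported,
#' not clipped, and flagged in the `qc_negative` column.
#'
#' @param series An [incubation_series()].
#' @param index Optional single interval index (1 = first interval, between
#'   events 1 and 2); returns just that flux as a number.
#' @return A `flux_series` data.frame with columns `t_start`, `t_end`, `dt`,
#'   `flux` (mmol m-2 d-1) and `qc_negative`, or a single numeric if
#'   `index` is given.
#' @export
interval_flux <- function(series, index = NULL) {
  stopifnot(inherits(series, "incubation_series"))
  n <- length(series$time_d)
  if (n < 2) stop("need at least 2 events to compute a flux", call. = FALSE)
  i <- 2:n
  start_umol <- start_inventory(series$conc_end[i - 1], series$v_olw[i - 1],
                                series$v_repl[i - 1],
                                series$conc_repl[i - 1])
  end_umol <- series$v_olw[i] * series$conc_end[i]
  dt <- series$time_d[i] - series$time_d[i - 1]
  flux <- (end_umol - start_umol) / 1000 / (series$core_area * dt)
  out <- data.frame(t_start = series$time_d[i - 1],
                    t_end = series$time_d[i], dt = dt, flux = flux,
                    qc_negative = flux < 0)
  class(out) <- c("flux_series", "data.frame")
  attr(out, "species") <- series$species
  attr(out, "core_id") <- series$core_id
  attr(out, "core_area") <- series$core_area
  if (!is.null(index)) {
    if (index < 1 || index > nrow(out)) {
      stop("interval index out of range", call. = FALSE)
    }
    return(out$flux[index])
  }
  out
}

#' Cumulative flux over an incubation
#'
#' Time-integral of the per-interval fluxes: sum of flux times interval
#' duration, in mmol m-2. This is the total amount released per unit
#' sediment area over the experiment.
#'
#' @param fluxes A `flux_series` from [interval_flux()] (an empty one gives
#'   0).
#' @return Cumulative flux in mmol m-2.
#' @export
cumulative_flux <- function(fluxes) {
  stopifnot(inherits(fluxes, "data.frame"))
  if (nrow(fluxes) == 0) return(0)
  sum(fluxes$flux * fluxes$dt)
}

#' Replicate mean and sample standard deviation
#'
#' @param values Numeric vector of per-core values (e.g. cumulative fluxes).
#' @return List with `mean`, `sd` (n-1 denominator; NA for a single value)
#'   and `n`.
#' @export
replicate_stats <- function(values) {
  if (length(values) < 1) stop("no values supplied", call. = FALSE)
  list(mean = mean(values),
       sd = if (length(values) > 1) stats::sd(values) else NA_real_,
       n = length(values))
}

#' First sampling time at which a solute was detected
#'
#' @param series An [incubation_series()].
#' @param detection_limit mmol m-3 (default 1).
#' @return The earliest sampling time (days) whose measured concentration
#'   exceeds the limit, or NA if never.
#' @export
detect_onset <- function(series, detection_limit = 1) {
  stopifnot(inherits(series, "incubation_series"))
  hit <- which(series$conc_end > detection_limit)
  if (length(hit) == 0) NA_real_ else series$time_d[hit[1]]
}

#' Flag overlying-water oxygen intrusions in an incubation
#'
#' Quality-control helper for the continuously logged O2 series of a
#' nominally anoxic incubation: returns the times at which O2 exceeded a
#' threshold.
#'
#' @param time_d,o2 Times (d) and O2 concentrations (mmol m-3).
#' @param threshold mmol m-3 (default 1).
#' @return Data.frame of offending `time_d` and `o2` rows (possibly empty).
#' @export
qc_oxygen <- function(time_d, o2, threshold = 1) {
  stopifnot(length(time_d) == length(o2))
  bad <- o2 > threshold
  data.frame(time_d = time_d[bad], o2 = o2[bad])
}
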