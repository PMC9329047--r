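# Delimited-text readers/writers, configuration, and the pipeline/CLI
# surface. Interchange format: comma-separated UTF-8 with a header row and
# "." decimal. Column schemas:
#   profiles:   core_id, campaign, species, depth_m, conc_uM
#   incubation: core_id, species, time_d, conc_uM, v_olw_L, v_repl_L,
#               conc_repl_uM
#   solids:     core_id, campaign, species, extraction, depth_top_m,
#               depth_bot_m, conc_umol_g

.check_columns <- function(df, required, what, path) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s file '%s' is missing column(s): %s", what, path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
}

.log_msg <- function(...) message(sprintf(...))

#' Read depth profiles from a CSV file
#'
#' One row per measurement; profiles are keyed by core and species. Rows
#' with non-monotone depth ordering are sorted on load with a warning.
#'
#' @param path CSV with columns `core_id`, `campaign`, `species`,
#'   `depth_m`, `conc_uM`.
#' @return Named list of [depth_profile()]s, keyed `core_id.species`.
#' @export
read_profiles <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .check_columns(df, c("core_id", "species", "depth_m", "conc_uM"),
                 "profile", path)
  if (!"campaign" %in% names(df)) df$campaign <- NA_character_
  keys <- paste(df$core_id, df$species, sep = ".")
  out <- lapply(split(df, keys), function(d) {
    if (is.unsorted(d$depth_m, strictly = TRUE)) {
      warning(sprintf("profile %s/%s: depths not sorted; sorting on load",
                      d$core_id[1], d$species[1]), call. = FALSE)
      d <- d[order(d$depth_m), ]
    }
    depth_profile(d$depth_m, d$conc_uM, species = d$species[1],
                  core_id = d$core_id[1], campaign = d$campaign[1])
  })
  .log_msg("read %d profile(s) (%d rows) from %s", length(out), nrow(df),
           path)
  out
}

#' Write depth profiles to a CSV file
#'
#' @param profiles A [depth_profile()] or list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  if (inherits(profiles, "depth_profile")) profiles <- list(profiles)
  rows <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(core_id = p$core_id, campaign = p$campaign,
               species = p$species, depth_m = p$depths,
               conc_uM = p$concentrations)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read incubation series from a CSV file
#'
#' @param path CSV with columns `core_id`, `species`, `time_d`, `conc_uM`,
#'   `v_olw_L`, `v_repl_L`, `conc_repl_uM`.
#' @param core_area Sediment surface area in m2 applied to every series.
#' @return Named list of [incubation_series()], keyed `core_id.species`.
#' @export
read_incubation <- function(path, core_area = 28.3e-4) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .check_columns(df, c("core_id", "species", "time_d", "conc_uM",
                       "v_olw_L", "v_repl_L", "conc_repl_uM"),
                 "incubation", path)
  keys <- paste(df$core_id, df$species, sep = ".")
  out <- lapply(split(df, keys), function(d) {
    d <- d[order(d$time_d), ]
    incubation_series(d$time_d, d$conc_uM, v_olw = d$v_olw_L,
                      v_repl = d$v_repl_L, conc_repl = d$conc_repl_uM,
                      species = d$species[1], core_id = d$core_id[1],
                      core_area = core_area)
  })
  .log_msg("read %d incubation series (%d rows) from %s", length(out),
           nrow(df), path)
  out
}

#' Write incubation series to a CSV file
#'
#' @param series An [incubation_series()] or list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_incubation <- function(series, path) {
  if (inherits(series, "incubation_series")) series <- list(series)
  rows <- do.call(rbind, lapply(series, function(s) {
    data.frame(core_id = s$core_id, species = s$species,
               time_d = s$time_d, conc_uM = s$conc_end,
               v_olw_L = s$v_olw, v_repl_L = s$v_repl,
               conc_repl_uM = s$conc_repl)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read solid-phase profiles from a CSV file
#'
#' @param path CSV with columns `core_id`, `campaign`, `species`,
#'   `extraction`, `depth_top_m`, `depth_bot_m`, `conc_umol_g`.
#' @return Named list of [solid_phase_profile()]s, keyed
#'   `core_id.species.extraction`.
#' @export
read_solids <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .check_columns(df, c("core_id", "species", "extraction", "depth_top_m",
                       "depth_bot_m", "conc_umol_g"), "solid-phase", path)
  if (!"campaign" %in% names(df)) df$campaign <- NA_character_
  keys <- paste(df$core_id, df$species, df$extraction, sep = ".")
  out <- lapply(split(df, keys), function(d) {
    d <- d[order(d$depth_top_m), ]
    solid_phase_profile(d$conc_umol_g, depth_top = d$depth_top_m,
                        depth_bot = d$depth_bot_m,
                        species = d$species[1],
                        extraction = d$extraction[1],
                        core_id = d$core_id[1], campaign = d$campaign[1])
  })
  .log_msg("read %d solid-phase profile(s) (%d rows) from %s",
           length(out), nrow(df), path)
  out
}

#' Write solid-phase profiles to a CSV file
#'
#' @param solids A [solid_phase_profile()] or list of them (boundary
#'   geometry only).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_solids <- function(solids, path) {
  if (inherits(solids, "solid_phase_profile")) solids <- list(solids)
  rows <- do.call(rbind, lapply(solids, function(s) {
    stopifnot(s$geometry == "boundaries")
    data.frame(core_id = s$core_id, campaign = s$campaign,
               species = s$species, extraction = s$extraction,
               depth_top_m = s$depth_top, depth_bot_m = s$depth_bot,
               conc_umol_g = s$conc)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Analysis configuration
#'
#' Builds a validated configuration, optionally overriding defaults from a
#' JSON file. Every defaulted value is echoed to the log.
#'
#' @param path Optional JSON file of overrides.
#' @param ... Named overrides applied after the file.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(path = NULL, ...) {
  cfg <- list(
    detection_limit = 1,          # mmol m-3, microsensor + onset detection
    gradient_points = 4,          # points per default gradient window
    core_area = 28.3e-4,          # m2
    solid_density = 2.6,          # g cm-3
    porosity = 0.85,
    salinity = 30,
    temperature = 4,              # degC
    mixed_layer_height = 15,      # m
    as_species = "HAsO4",
    inventory_interval = c(0, 0.01),  # m, "upper 1 cm"
    seed = 1
  )
  if (!is.null(path)) {
    if (!file.exists(path)) stop("no such config file: ", path,
                                 call. = FALSE)
    over <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown) > 0) {
      stop("unknown config key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    cfg[names(over)] <- over
  }
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(dots)] <- dots
  stopifnot(cfg$detection_limit > 0, cfg$core_area > 0,
            cfg$mixed_layer_height > 0, cfg$gradient_points >= 2,
            cfg$porosity > 0, cfg$porosity < 1)
  defaulted <- setdiff(names(cfg), names(c(
    if (is.null(path)) NULL else over, dots)))
  if (length(defaulted) > 0) {
    .log_msg("config defaults in effect: %s",
             paste(defaulted, collapse = ", "))
  }
  structure(cfg, class = "analysis_config")
}

#' Run the full analysis pipeline on a data directory
#'
#' Reads `profiles.csv`, `incubation.csv` and `solids.csv` from `input_dir`
#' (each optional, but at least one must be present), runs feature
#' extraction, profile fluxes and peak partitioning, incubation fluxes
#' with cumulative totals, replicate statistics and sulfide onset, and
#' solid-phase inventories, then writes `results.csv` (long format) and
#' `report.txt` to `out_dir`.
#'
#' @param input_dir Directory with the input CSVs.
#' @param out_dir Output directory (created if needed).
#' @param config An [analysis_config()].
#' @return The results data.frame, invisibly.
#' @export
run_pipeline <- function(input_dir, out_dir,
                         config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  options(benthicflux.as_species = config$as_species)
  props <- sediment_properties(config$porosity,
                               solid_density = config$solid_density,
                               salinity = config$salinity,
                               temperature = config$temperature)
  paths <- file.path(input_dir, c("profiles.csv", "incubation.csv",
                                  "solids.csv"))
  names(paths) <- c("profiles", "incubation", "solids")
  present <- stats::setNames(file.exists(paths), names(paths))
  if (!any(present)) {
    stop("no input files found in '", input_dir,
         "' (expected profiles.csv, incubation.csv and/or solids.csv)",
         call. = FALSE)
  }
  res <- list()
  add <- function(stage, core_id, species, quantity, value, unit) {
    res[[length(res) + 1]] <<- data.frame(
      stage = stage, core_id = core_id, species = species,
      quantity = quantity, value = value, unit = unit)
  }

  if (present["profiles"]) {
    profs <- tryCatch(read_profiles(paths["profiles"]),
                      error = function(e) stop("[profiles] ",
                                               conditionMessage(e),
                                               call. = FALSE))
    by_core <- split(profs, vapply(profs, `[[`, "", "core_id"))
    for (core in names(by_core)) {
      pl <- by_core[[core]]
      sp <- vapply(pl, `[[`, "", "species")
      pick <- function(name) {
        i <- match(name, sp)
        if (is.na(i)) NULL else pl[[i]]
      }
      o2 <- pick("O2"); h2s <- pick("SumH2S"); ph <- pick("pH")
      if (!is.null(o2) || !is.null(h2s) || !is.null(ph)) {
        ft <- extract_features(o2, h2s, ph,
                               detection_limit = config$detection_limit)
        add("features", core, "O2", "OPD", ft$opd, "m")
        add("features", core, "SumH2S", "SAD", ft$sad, "m")
        add("features", core, "", "suboxic_thickness",
            ft$suboxic_thickness, "m")
        if (!is.na(ft$ph_max)) {
          add("features", core, "pH", "pH_max", ft$ph_max, "pH")
          add("features", core, "pH", "pH_min", ft$ph_min, "pH")
        }
      }
      for (solute in intersect(c("dFe", "dAs"), sp)) {
        prof <- pl[[match(solute, sp)]]
        fx <- diffusive_flux(prof, props,
                             n_points = config$gradient_points)
        add("profile_flux", core, solute, "swi_flux", fx$flux,
            "mmol m-2 d-1")
        pp <- tryCatch(peak_partition(prof, props,
                                      config$gradient_points),
                       error = function(e) NULL)
        if (!is.null(pp)) {
          add("profile_flux", core, solute, "production", pp$production,
              "mmol m-2 d-1")
          add("profile_flux", core, solute, "upward_fraction",
              pp$upward_fraction, "fraction")
        }
      }
    }
  }

  if (present["incubation"]) {
    incs <- tryCatch(read_incubation(paths["incubation"],
                                     core_area = config$core_area),
                     error = function(e) stop("[incubation] ",
                                              conditionMessage(e),
                                              call. = FALSE))
    cums <- list()
    for (s in incs) {
      fs <- interval_flux(s)
      cum <- cumulative_flux(fs)
      add("incubation", s$core_id, s$species, "cumulative_flux", cum,
          "mmol m-2")
      add("incubation", s$core_id, s$species, "max_flux", max(fs$flux),
          "mmol m-2 d-1")
      onset <- detect_onset(s, config$detection_limit)
      add("incubation", s$core_id, s$species, "onset_time", onset, "d")
      cums[[s$species]] <- c(cums[[s$species]], cum)
    }
    for (sp in names(cums)) {
      st <- replicate_stats(cums[[sp]])
      add("incubation", "all", sp, "cumulative_mean", st$mean, "mmol m-2")
      add("incubation", "all", sp, "cumulative_sd", st$sd, "mmol m-2")
    }
    if ("dAs" %in% names(cums)) {
      conc <- mixed_layer_concentration(range(cums$dAs),
                                        config$mixed_layer_height)
      add("budget", "all", "dAs", "mixed_layer_conc_min", conc[1], "nM")
      add("budget", "all", "dAs", "mixed_layer_conc_max", conc[2], "nM")
    }
  }

  if (present["solids"]) {
    sols <- tryCatch(read_solids(paths["solids"]),
                     error = function(e) stop("[solids] ",
                                              conditionMessage(e),
                                              call. = FALSE))
    for (s in sols) {
      inv <- solid_inventory(s, props, config$inventory_interval[1],
                             config$inventory_interval[2])
      add("inventory", s$core_id, s$species,
          paste0("inventory_", s$extraction), inv, "mmol m-2")
    }
  }

  results <- do.call(rbind, res)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(results, file.path(out_dir, "results.csv"),
                   row.names = FALSE)
  rpt <- file.path(out_dir, "report.txt")
  lines <- c("benthicflux pipeline report",
             sprintf("input: %s", normalizePath(input_dir)),
             sprintf("sediment: phi %.3f, rho_s %.2f g cm-3, S %.1f, T %.1f C",
                     config$porosity, config$solid_density,
                     config$salinity, config$temperature),
             sprintf("dAs modelled as %s", config$as_species),
             "",
             utils::capture.output(print(results, row.names = FALSE)))
  writeLines(lines, rpt)
  .log_msg("wrote %s and %s", file.path(out_dir, "results.csv"), rpt)
  invisible(results)
}

#' Write a simulated scenario to the interchange formats
#'
#' Generates a seasonal scenario ([make_scenario()] plus
#' [make_incubation_scenario()]) and writes `profiles.csv`,
#' `incubation.csv`, `solids.csv` and a `truth.json` record to a
#' directory, ready for [run_pipeline()].
#'
#' @param preset `"march"`, `"may"` or `"august"`.
#' @param out_dir Output directory.
#' @param seed RNG seed.
#' @param noise_cv Measurement noise CV.
#' @return `out_dir`, invisibly.
#' @export
simulate_to_dir <- function(preset, out_dir, seed = 1, noise_cv = 0) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sc <- make_scenario(preset, seed = seed, noise_cv = noise_cv)
  inc <- make_incubation_scenario(preset, seed = seed, noise_cv = noise_cv)
  write_profiles(Filter(Negate(is.null), sc$profiles),
                 file.path(out_dir, "profiles.csv"))
  series <- unlist(lapply(c("dFe", "SumH2S", "dAs"), function(sp) {
    lapply(inc[[sp]], `[[`, "series")
  }), recursive = FALSE)
  write_incubation(series, file.path(out_dir, "incubation.csv"))
  write_solids(sc$solids, file.path(out_dir, "solids.csv"))
  truth <- list(scenario = sc$truth,
                incubation = lapply(c("dFe", "SumH2S", "dAs"), function(sp) {
                  lapply(inc[[sp]], function(x) x$truth[
                    c("total_released_mmol", "cumulative_mmol_m2")])
                }),
                core_factors = inc$core_factors)
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  .log_msg("simulated '%s' scenario written to %s", preset, out_dir)
  invisible(out_dir)
}

#' Command-line entry point
#'
#' Dispatches the subcommands `simulate`, `features`, `profile-flux`,
#' `incubation`, `inventory`, `budget` and `run`. Flags: `--in`, `--out`,
#' `--preset`, `--seed`, `--config`. Intended for use through the
#' installed `exec/benthicflux` script; returns the exit status instead of
#' calling `quit()` so it is testable in-process.
#'
#' @param args Character vector of CLI arguments (default:
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Integer exit status, invisibly (0 on success).
#' @export
benthicflux_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: benthicflux <simulate|features|profile-flux|incubation|",
    "inventory|budget|run> [--in DIR] [--out DIR] [--preset NAME]",
    "[--seed N] [--config FILE]")
  flag <- function(name, default = NULL) {
    i <- which(args == paste0("--", name))
    if (length(i) == 0) return(default)
    if (i == length(args)) stop("missing value for --", name, call. = FALSE)
    args[i + 1]
  }
  status <- tryCatch({
    if (length(args) == 0) stop(usage, call. = FALSE)
    cmd <- args[1]
    cfg <- analysis_config(path = flag("config"))
    seed <- as.integer(flag("seed", cfg$seed))
    input <- flag("in", ".")
    out <- flag("out", "benthicflux-out")
    switch(cmd,
      simulate = simulate_to_dir(flag("preset", "march"), out,
                                 seed = seed),
      run = run_pipeline(input, out, cfg),
      features = ,
      `profile-flux` = {
        profs <- read_profiles(file.path(input, "profiles.csv"))
        tmp <- tempfile(); on.exit(unlink(tmp), add = TRUE)
        dir.create(tmp)
        file.copy(file.path(input, "profiles.csv"), tmp)
        run_pipeline(tmp, out, cfg)
      },
      incubation = ,
      budget = {
        tmp <- tempfile(); on.exit(unlink(tmp), add = TRUE)
        dir.create(tmp)
        file.copy(file.path(input, "incubation.csv"), tmp)
        run_pipeline(tmp, out, cfg)
      },
      inventory = {
        tmp <- tempfile(); on.exit(unlink(tmp), add = TRUE)
        dir.create(tmp)
        file.copy(file.path(input, "solids.csv"), tmp)
        run_pipeline(tmp, out, cfg)
      },
      stop("unknown subcommand '", cmd, "'\n", usage, call. = FALSE)
    )
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
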