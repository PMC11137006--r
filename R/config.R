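#' Default experiment configuration
#'
#' Builds the full parameterisation of one simulation run.  Defaults are the
#' reference parameter set of the model: a 1000^3 um domain meshed with 20 um
#' voxels, a 30-day run saved every 1400 min, the three-clock hierarchy
#' (cycle 6 min, mechanics 0.1 min, diffusion 0.01 min), hepatocellular
#' cycle-phase durations, and the CAR T-cell block (kill rate 0.06/min,
#' adhesion rate 0.2/min, attachment timeout 60 min, speed 2 um/min, bias 0.5,
#' persistence 10 min, lifespan 10 +/- 5 days).
#'
#' Time-like parameters are in minutes unless the name says otherwise
#' (`lifespan_*` are in days, dose days in days); lengths in um; oxygen in
#' mmHg; the immunostimulatory factor is in arbitrary units (only its gradient
#' direction matters).
#'
#' @param ... named overrides of any default key. Unknown keys are rejected
#'   with a suggestion of the nearest valid key.
#' @return A named list with class `cartsim_config`.
#' @examples
#' cfg <- experiment_config(n_cells = 100, t_total = 1440)
#' cfg$kill_rate
#' @export
experiment_config <- function(...) {
  cfg <- default_config_values()
  overrides <- list(...)
  if (length(overrides) > 0 &&
      (is.null(names(overrides)) || any(names(overrides) == ""))) {
    abort("configuration overrides must be named")
  }
  if (anyDuplicated(names(overrides))) {
    abort(sprintf("duplicated configuration key '%s'",
                  names(overrides)[duplicated(names(overrides))][1]))
  }
  for (key in names(overrides)) {
    if (!key %in% names(cfg)) {
      near <- names(cfg)[which.min(utils::adist(key, names(cfg)))]
      abort(sprintf("unknown configuration key '%s'; did you mean '%s'?",
                    key, near))
    }
    cfg[[key]] <- overrides[[key]]
  }
  cfg <- structure(cfg, class = "cartsim_config")
  validate_config(cfg)
  cfg
}

default_config_values <- function() {
  list(
    # time hierarchy (minutes)
    t_total = 43200, t_save = 1400,
    dt_cycle = 6, dt_mech = 0.1, dt_diff = 0.01, t_v_steps = 20,
    # domain and meshes (um)
    domain_size = 1000, voxel_size = 20, mech_voxel_size = 30,
    # substrates
    oxygen_diffusion = 1e5, oxygen_decay = 0.1,
    oxygen_init = 38, oxygen_boundary = 38,
    if_diffusion = 1e3, if_decay = 0.016, if_init = 0, if_saturation = 1,
    # cell geometry and mechanics
    cell_radius = 8.4, nu = 1,
    repulsion_cancer = 10, repulsion_tcell = 5,
    adhesion_strength = 0.4, adhesion_distance_scale = 1.25,
    # exchange rates (1/min)
    oxygen_uptake_cancer = 10, oxygen_uptake_tcell = 1, if_secretion = 10,
    # cycle phase mean durations (minutes)
    T_G1 = 20.4 * 60, T_S = 13.6 * 60, T_G2 = 3.0 * 60, T_M = 1.6 * 60,
    fixed_phase_durations = FALSE,
    # oxygen response (mmHg) and necrosis
    o2_proliferation_arrest = 5, o2_proliferation_saturation = 10,
    o2_necrosis_threshold = 5, tau_necrosis = 360,
    # volume relaxation (1/min)
    volume_rate = 0.004, volume_rate_apoptosis = 1 / 60,
    volume_rate_necrosis = 1 / 720, removal_fraction = 0.05,
    # intratumour heterogeneity
    oncoprotein_mean = 1, oncoprotein_sd = 0.25,
    oncoprotein_min = 0, oncoprotein_max = 2, recognition_threshold = 0.5,
    # CAR T-cell block
    kill_rate = 0.06, attachment_time = 60, adhesion_rate = 0.2,
    max_adhesion_distance = 18, migration_speed = 2, migration_bias = 0.5,
    persistence_time = 10, lifespan_mean = 10, lifespan_sd = 5,
    angles_uniform = FALSE,
    # modes
    recognition_mode = "antigen_specific", persistence_mode = "standard",
    # dosing schedule (days, CAR T : cancer ratios)
    dose_days = numeric(0), dose_ratios = numeric(0),
    # organoid fixture
    n_cells = 3963,
    seed = 1L
  )
}

#' Validate an experiment configuration
#'
#' Checks the clock hierarchy, mesh commensurability, dosing schedule and
#' parameter ranges; violations are rejected naming the offending keys.
#'
#' @param cfg a `cartsim_config` list.
#' @return `cfg`, invisibly, if valid.
#' @export
validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) abort(paste0("invalid configuration: ", msg))
  chk(cfg$dt_diff > 0 && cfg$dt_mech > 0 && cfg$dt_cycle > 0,
      "dt_diff, dt_mech, dt_cycle must be positive")
  chk(cfg$dt_diff <= cfg$dt_mech && cfg$dt_mech <= cfg$dt_cycle,
      "clock hierarchy requires dt_diff <= dt_mech <= dt_cycle")
  chk(abs(cfg$dt_cycle / cfg$dt_mech - round(cfg$dt_cycle / cfg$dt_mech)) < 1e-8,
      "dt_cycle must be an integer multiple of dt_mech")
  chk(abs(cfg$dt_mech / cfg$dt_diff - round(cfg$dt_mech / cfg$dt_diff)) < 1e-8,
      "dt_mech must be an integer multiple of dt_diff")
  chk(cfg$t_save >= cfg$dt_cycle, "t_save must be at least dt_cycle")
  chk(cfg$t_total >= cfg$dt_cycle, "t_total must be at least dt_cycle")
  chk(abs(cfg$domain_size / cfg$voxel_size -
            round(cfg$domain_size / cfg$voxel_size)) < 1e-8,
      "domain_size must be an integer multiple of voxel_size")
  chk(cfg$cell_radius > 0, "cell_radius must be positive")
  chk(cfg$adhesion_distance_scale > 1,
      "adhesion_distance_scale must exceed 1 (R_A > R_cell)")
  chk(cfg$oncoprotein_min < cfg$oncoprotein_max,
      "oncoprotein support must be a non-degenerate interval")
  chk(length(cfg$dose_days) == length(cfg$dose_ratios),
      "dose_days and dose_ratios must have equal length")
  if (length(cfg$dose_days) > 0) {
    chk(all(cfg$dose_days >= 0), "dose_days must be >= 0")
    chk(!is.unsorted(cfg$dose_days, strictly = TRUE),
        "dose_days must be strictly increasing")
    chk(all(cfg$dose_ratios > 0), "dose_ratios must be positive")
    chk(all(cfg$dose_days * 1440 <= cfg$t_total),
        "dose_days must fall inside the simulation window")
  }
  chk(cfg$recognition_mode %in% c("antigen_specific", "multi_antigen"),
      "recognition_mode must be 'antigen_specific' or 'multi_antigen'")
  chk(cfg$persistence_mode %in% c("standard", "long_term"),
      "persistence_mode must be 'standard' or 'long_term'")
  chk(cfg$migration_bias >= 0 && cfg$migration_bias <= 1,
      "migration_bias must lie in [0, 1]")
  invisible(cfg)
}

#' Desk-scale experiment preset
#'
#' Scales the reference configuration down to a workstation-friendly smoke
#' scale: a 300^3 um domain, a few hundred seeded cells, a few simulated days,
#' daily saves, and the diffusion step relaxed to 0.05 min (the implicit
#' solver is unconditionally stable; accuracy at the relaxed step is asserted
#' against the 0.01-min reference in the test suite).
#'
#' @param n_cells organoid size at seeding.
#' @param days simulated duration in days.
#' @param t_save save cadence (min).
#' @param dt_diff diffusion step (min).
#' @param ... further overrides passed to [experiment_config()].
#' @return A `cartsim_config`.
#' @export
desk_config <- function(n_cells = 500, days = 3, t_save = 720,
                        dt_diff = 0.05, ...) {
  experiment_config(
    domain_size = 300, n_cells = n_cells,
    t_total = days * 1440, t_save = t_save, dt_diff = dt_diff,
    ...
  )
}

#' @export
print.cartsim_config <- function(x, ...) {
  cat("<cartsim_config>\n")
  cat(sprintf("  domain %g um, %d cells seeded, %g simulated days\n",
              x$domain_size, x$n_cells, x$t_total / 1440))
  cat(sprintf("  clocks (min): cycle %g / mechanics %g / diffusion %g\n",
              x$dt_cycle, x$dt_mech, x$dt_diff))
  if (length(x$dose_days) > 0) {
    cat(sprintf("  doses: %s\n",
                paste(sprintf("day %g ratio %g", x$dose_days, x$dose_ratios),
                      collapse = ", ")))
  } else {
    cat("  doses: none (untreated control)\n")
  }
  cat(sprintf("  recognition %s, persistence %s, seed %d\n",
              x$recognition_mode, x$persistence_mode, as.integer(x$seed)))
  invisible(x)
}

#' Read a configuration file
#'
#' Reads a YAML configuration; keys missing from the file are filled with the
#' reference defaults, unknown keys are rejected with the nearest valid key,
#' and the result is validated.
#'
#' @param path path to a YAML file.
#' @return A `cartsim_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("configuration file '%s' not found", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  raw$dose_days <- as.numeric(raw$dose_days %||% numeric(0))
  raw$dose_ratios <- as.numeric(raw$dose_ratios %||% numeric(0))
  do.call(experiment_config, raw)
}

#' Write a configuration file
#'
#' @param cfg a `cartsim_config`.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  validate_config(cfg)
  yaml::write_yaml(unclass(cfg), path, precision = 15)
  invisible(path)
}
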