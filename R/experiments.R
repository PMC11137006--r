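#' Seed a spherical organoid
#'
#' Places cancer cells on a jittered face-centred-cubic packing filling a
#' sphere at the domain centre, trimmed to exactly the target count (keeping
#' the innermost lattice sites).  Each cell receives an independent
#' oncoprotein draw from the truncated normal, an initial volume of
#' `4/3 pi R_cell^3`, a cycle phase sampled proportional to the phase mean
#' durations and a uniformly random phase clock (used by the fixed-duration
#' cycle mode).
#'
#' @param n target cell count.
#' @param cfg a `cartsim_config`; supplies the cell radius, the domain and
#'   the heterogeneity parameters.
#' @param jitter lattice jitter amplitude as a fraction of the
#'   nearest-neighbour spacing (kept small so the minimum initial pairwise
#'   separation stays above 1.8 cell radii).
#' @return A tibble of cancer cells: `x`, `y`, `z`, `volume`, `radius`, `o`,
#'   `type`, `phase`, `phase_clock`, `death`.
#' @examples
#' cells <- seed_organoid(50, desk_config(n_cells = 50))
#' nrow(cells)
#' @export
seed_organoid <- function(n, cfg = experiment_config(), jitter = 0.025) {
  stopifnot(n >= 1)
  R <- cfg$cell_radius
  d0 <- 2 * R                          # nearest-neighbour spacing
  a <- d0 * sqrt(2)                    # cubic lattice constant
  centre <- rep(cfg$domain_size / 2, 3)
  # number density of fcc is 4 / a^3; radius of a sphere holding n sites
  r_sphere <- (3 * n / (4 * pi * (4 / a^3)))^(1 / 3) + a
  if (r_sphere + R > cfg$domain_size / 2) {
    abort("organoid sphere exceeds the domain; enlarge domain_size or reduce n")
  }
  m <- ceiling(r_sphere / a)
  base <- as.matrix(expand.grid(i = -m:m, j = -m:m, k = -m:m)) * a
  offsets <- rbind(c(0, 0, 0), c(0, a / 2, a / 2),
                   c(a / 2, 0, a / 2), c(a / 2, a / 2, 0))
  pts <- do.call(rbind, lapply(seq_len(4), function(q) {
    sweep(base, 2, offsets[q, ], "+")
  }))
  pts <- pts + matrix(runif(length(pts), -jitter * d0, jitter * d0),
                      nrow(pts), 3)
  r2 <- rowSums(pts^2)
  keep <- order(r2)[seq_len(n)]        # trim outermost lattice sites first
  pts <- sweep(pts[keep, , drop = FALSE], 2, centre, "+")
  durations <- c(cfg$T_G1, cfg$T_S, cfg$T_G2, cfg$T_M)
  phase <- sample.int(4, n, replace = TRUE, prob = durations)
  o <- sample_oncoprotein(n, cfg$oncoprotein_mean, cfg$oncoprotein_sd,
                          cfg$oncoprotein_min, cfg$oncoprotein_max)
  tibble::tibble(
    x = pts[, 1], y = pts[, 2], z = pts[, 3],
    volume = cell_volume(R), radius = R,
    o = o, type = classify_type(pmin(o, 2)),
    phase = phase,
    phase_clock = runif(n) * durations[phase],
    death = "none"
  )
}

#' Run one simulation experiment
#'
#' Executes the full multiscale loop: every cycle step (6 min) applies dose
#' checks, cycle progression, death processes and volume relaxation; nested
#' mechanics steps (0.1 min) apply CAR T-cell migration, adhesion and kill
#' attempts, exhaustion and position updates with the neighbour list
#' refreshed every `t_v_steps` steps; nested diffusion steps (0.01 min)
#' advance the reaction-diffusion fields with per-cell secretion and uptake.
#' Aggregate observables are appended at every save time.  Runs are fully
#' reproducible: the configuration's `seed` drives every random draw.
#'
#' @param cfg a `cartsim_config`.
#' @param init optional initial cancer population (from [seed_organoid()]);
#'   seeded from `cfg` when omitted.
#' @param save_snapshots record point-cloud snapshots at every save time (in
#'   memory); the final populations are always returned.
#' @return A `cart_sim` object: a list with `metrics` (tibble, one row per
#'   save time), `kill_ledger` (one row per administered T-cell),
#'   `kills_by_type`, `final_cancer`, `final_tcells`, `counters`, `config`,
#'   and optional `snapshots`.
#' @examples
#' \donttest{
#' cfg <- desk_config(n_cells = 60, days = 0.5, seed = 7)
#' sim <- simulate_organoid(cfg)
#' tidy(sim)
#' }
#' @export
simulate_organoid <- function(cfg, init = NULL, save_snapshots = FALSE) {
  validate_config(cfg)
  set.seed(as.integer(cfg$seed))
  if (is.null(init)) init <- seed_organoid(cfg$n_cells, cfg)
  ecfg <- unclass(cfg)
  ecfg$oxygen_boundary <- if (is.na(cfg$oxygen_boundary)) -1 else
    cfg$oxygen_boundary
  res <- cpp_run_engine(
    ecfg,
    list(x = init$x, y = init$y, z = init$z, o = init$o,
         volume = init$volume, phase = as.integer(init$phase),
         phase_clock = init$phase_clock),
    save_snapshots
  )
  metrics <- tibble::as_tibble(res$metrics)
  ledger <- tibble::as_tibble(res$kill_ledger)
  if (length(cfg$dose_days) > 0) {
    dk <- res$dose_kills
    colnames(dk) <- paste0("kills_dose", seq_len(ncol(dk)))
    metrics <- dplyr::bind_cols(metrics, tibble::as_tibble(dk))
  }
  structure(
    list(
      metrics = metrics,
      kill_ledger = ledger,
      kills_by_type = setNames(res$kills_by_type, paste0("type", 1:4)),
      final_cancer = tibble::as_tibble(res$final_cancer) |>
        dplyr::mutate(
          type = classify_type(pmin(.data$oncoprotein, 2)),
          death = c("none", "apoptosis", "necrosis")[.data$death + 1]
        ),
      final_tcells = tibble::as_tibble(res$final_tcells),
      counters = res$counters,
      snapshots = if (save_snapshots) {
        purrr::map2(res$snapshots, res$snapshot_times, function(s, t) {
          list(time = t,
               cancer = tibble::as_tibble(s$cancer),
               tcells = tibble::as_tibble(s$tcells))
        })
      },
      config = cfg
    ),
    class = "cart_sim"
  )
}

#' @export
print.cart_sim <- function(x, ...) {
  last <- tail(x$metrics, 1)
  cat("<cart_sim>\n")
  cat(sprintf("  %g simulated days, %d save points\n",
              x$config$t_total / 1440, nrow(x$metrics)))
  cat(sprintf("  final: %d live cancer cells, %d cumulative dead, mean o %.3f\n",
              last$live_cancer, last$cum_dead, last$mean_oncoprotein))
  if (nrow(x$kill_ledger) > 0) {
    dpc <- dead_per_cart(x)
    cat(sprintf("  CAR T: %d administered, %d kills, %.2f dead/CAR-T, %d free\n",
                nrow(x$kill_ledger), as.integer(sum(x$kill_ledger$kills)),
                dpc$ratio, dpc$free_tcells))
  }
  invisible(x)
}

#' Organoid growth rate
#'
#' Least-squares slope of `log(live cancer count)` against time over a
#' trailing window, reported per day.  An exact exponential sampled at the
#' save times is recovered to machine precision; a window containing a zero
#' count has no defined log-linear growth rate and is flagged with a warning
#' and an `NA` return.
#'
#' @param metrics a metrics tibble (from a `cart_sim`) or a `cart_sim`.
#' @param window trailing window length in days.
#' @return Growth rate in 1/day (`NA` if undefined).
#' @export
growth_rate <- function(metrics, window = 5) {
  if (inherits(metrics, "cart_sim")) metrics <- metrics$metrics
  t_end <- max(metrics$time)
  w <- metrics[metrics$time >= t_end - window * 1440 - 1e-9, ]
  if (nrow(w) < 3) abort("growth window must contain at least 3 save points")
  if (any(w$live_cancer == 0)) {
    warn("window contains a zero cancer-cell count; growth rate undefined")
    return(NA_real_)
  }
  fit <- lm(log(live_cancer) ~ time, data = w)
  unname(coef(fit)[2]) * 1440
}

#' Dead cancer cells per CAR T-cell
#'
#' The cumulative number of T-cell-attributed kills divided by the total
#' number of CAR T-cells administered, with the count of free CAR T-cells
#' (administered cells that never killed) reported alongside.  A ratio below
#' 1 implies, by pigeonhole on integer kill counts, that at least one
#' administered T-cell killed nothing.
#'
#' @param sim a `cart_sim`, or a kill-ledger tibble with a `kills` column.
#' @return A one-row tibble: `kills`, `tcells`, `ratio`, `free_tcells`.
#' @export
dead_per_cart <- function(sim) {
  ledger <- if (inherits(sim, "cart_sim")) sim$kill_ledger else sim
  if (nrow(ledger) == 0) abort("no CAR T-cells were administered")
  tibble::tibble(
    kills = sum(ledger$kills),
    tcells = nrow(ledger),
    ratio = sum(ledger$kills) / nrow(ledger),
    free_tcells = sum(ledger$kills == 0)
  )
}

#' Radial distribution of cell classes
#'
#' Number density of each cell class in concentric spherical shells about
#' the live-cancer-cell centre of mass.  Live cells are classed by type
#' (1..4); dead cells (whether killed by T-cells or necrotic from oxygen
#' deprivation) form their own class.  The default shell width is about five
#' cell radii.
#'
#' @param population a data frame with `x`, `y`, `z`, `type` and `death`
#'   columns (e.g. `final_cancer` of a `cart_sim`).
#' @param shell_width shell width Delta r (um).
#' @param R_cell cell radius used for the default shell width.
#' @return A tibble with one row per (shell, class): inner/outer radii,
#'   class, count and number density (cells/um^3).
#' @export
radial_distribution <- function(population, shell_width = 5 * R_cell,
                                R_cell = 8.4) {
  stopifnot(nrow(population) > 0, shell_width > 0)
  alive <- population$death == "none"
  ref <- if (any(alive)) population[alive, ] else population
  com <- c(mean(ref$x), mean(ref$y), mean(ref$z))
  r <- sqrt((population$x - com[1])^2 + (population$y - com[2])^2 +
              (population$z - com[3])^2)
  cls <- ifelse(population$death == "none",
                paste0("type", population$type), "dead")
  nshell <- max(1, ceiling(max(r) / shell_width + 1e-12))
  shell <- pmin(nshell, floor(r / shell_width) + 1)
  tidyr::expand_grid(
    shell = seq_len(nshell),
    class = c(paste0("type", 1:4), "dead")
  ) |>
    dplyr::left_join(
      tibble::tibble(shell = shell, class = cls) |>
        dplyr::count(.data$shell, .data$class),
      by = c("shell", "class")
    ) |>
    dplyr::mutate(
      count = tidyr::replace_na(.data$n, 0L),
      r_inner = (.data$shell - 1) * shell_width,
      r_outer = .data$shell * shell_width,
      r_mid = (.data$r_inner + .data$r_outer) / 2,
      volume = 4 / 3 * pi * (.data$r_outer^3 - .data$r_inner^3),
      density = .data$count / .data$volume
    ) |>
    dplyr::select("shell", "r_inner", "r_mid", "r_outer", "class",
                  "count", "density")
}

#' Minimum live cancer count over an initial window
#'
#' The depth of the therapy-induced nadir before a cutoff day.  Early
#' minima separate dose ratios by their kill *speed*, which is the
#' dose-ordered observable at small organoid sizes (given enough time, any
#' effective dose grinds a small organoid down to its unrecognisable
#' residue, so late minima converge across ratios).
#'
#' @param metrics a metrics tibble or `cart_sim`.
#' @param before_day only save points at or before this day count.
#' @return Minimum live cancer count in the window.
#' @export
min_live_before <- function(metrics, before_day = Inf) {
  if (inherits(metrics, "cart_sim")) metrics <- metrics$metrics
  min(metrics$live_cancer[metrics$time <= before_day * 1440 + 1e-9])
}

#' Run a replicate sweep over dose ratios
#'
#' Convenience driver for dose-scan experiments: runs one simulation per
#' (ratio, replicate) pair with distinct seeds and returns glance summaries.
#'
#' @param base_cfg a `cartsim_config` template (its dose schedule is
#'   replaced).
#' @param ratios CAR T : cancer dose ratios (0 means untreated control).
#' @param replicates replicates per ratio.
#' @param dose_day day of the (single) dose.
#' @param seed0 base seed; replicate r of ratio index k runs with seed
#'   `seed0 + 1000 * k + r`.
#' @param min_before_day cutoff day for the early tumour minimum column
#'   (see [min_live_before()]).
#' @return A tibble with one row per run: ratio, replicate, seed, the
#'   [glance()] summary columns, and `early_min_live_cancer`.
#' @export
sweep_doses <- function(base_cfg, ratios, replicates = 1, dose_day = 1,
                        seed0 = base_cfg$seed, min_before_day = 2) {
  grid <- tidyr::expand_grid(k = seq_along(ratios), rep = seq_len(replicates))
  purrr::pmap_dfr(grid, function(k, rep) {
    ratio <- ratios[k]
    cfg <- base_cfg
    cfg$seed <- as.integer(seed0 + 1000 * k + rep)
    if (ratio > 0) {
      cfg$dose_days <- dose_day
      cfg$dose_ratios <- ratio
    } else {
      cfg$dose_days <- numeric(0)
      cfg$dose_ratios <- numeric(0)
    }
    sim <- simulate_organoid(cfg)
    dplyr::bind_cols(
      tibble::tibble(ratio = ratio, replicate = rep, seed = cfg$seed),
      glance(sim),
      tibble::tibble(
        early_min_live_cancer = min_live_before(sim, min_before_day)
      )
    )
  })
}
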