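#' Advance the stochastic cell cycle
#'
#' The cycle is a directed graph G1 -> S -> G2 -> M -> (division -> G1).
#' Phase exit is memoryless: per step of length `dt` a cell leaves its phase
#' with probability `dt / T_phase_effective`.  Oncoprotein expression and
#' oxygen scale only the G1 exit rate, `T_G1_eff = T_G1 / (o * f(O2))`, where
#' `f` ramps linearly from 0 at the proliferation-arrest oxygen threshold to
#' 1 at the saturation threshold; S, G2 and M are unscaled.  Cells held by an
#' attached CAR T-cell (`attached`) freeze their phase clock entirely.  Cells
#' leaving M are flagged for division (`divide_now`).
#'
#' @param cells a data frame with columns `phase` (integer 1..4 for
#'   G1, S, G2, M) and `o` (oncoprotein in \[0, 2\]).
#' @param dt cycle time step (min), default 6.
#' @param o2 local oxygen per cell (mmHg); scalar recycled.
#' @param attached logical per cell; frozen cells do not progress.
#' @param cfg a `cartsim_config` supplying phase durations and oxygen
#'   thresholds.
#' @return `cells` with updated `phase` and a logical `divide_now` column.
#' @export
advance_cycle <- function(cells, dt = 6, o2 = Inf, attached = FALSE,
                          cfg = experiment_config()) {
  if (any(cells$o < 0 | cells$o > 2)) {
    abort("oncoprotein values must lie in [0, 2]")
  }
  n <- nrow(cells)
  o2 <- rep_len(o2, n)
  attached <- rep_len(attached, n)
  f_o2 <- pmin(1, pmax(0, (o2 - cfg$o2_proliferation_arrest) /
                         (cfg$o2_proliferation_saturation -
                            cfg$o2_proliferation_arrest)))
  durations <- c(cfg$T_G1, cfg$T_S, cfg$T_G2, cfg$T_M)
  t_eff <- durations[cells$phase]
  g1 <- cells$phase == 1L
  scale <- cells$o * f_o2
  t_eff[g1] <- ifelse(scale[g1] > 0, cfg$T_G1 / scale[g1], Inf)
  p_exit <- ifelse(is.finite(t_eff), pmin(1, dt / t_eff), 0)
  exits <- !attached & runif(n) < p_exit
  cells$divide_now <- exits & cells$phase == 4L
  cells$phase <- ifelse(exits & !cells$divide_now, cells$phase + 1L,
                        ifelse(cells$divide_now, 1L, cells$phase))
  cells
}

#' Divide flagged cells
#'
#' Each mother at M exit is replaced by two daughters: each receives half the
#' mother's volume (volume is conserved across the division instant), both
#' inherit the mother's oncoprotein exactly (no mutation at division; clonal
#' expansion of high-expression cells emerges from selection alone), and the
#' pair is offset +/- `R_cell / 2` along an axis drawn uniformly on the
#' sphere.  CAR T-cells never divide (divisions allowed = 0).
#'
#' @param cells a data frame with `x`, `y`, `z`, `volume`, `o`, `phase`, and
#'   a logical `divide_now` column (from [advance_cycle()]).
#' @param R_cell reference cell radius (um), used for the daughter offset.
#' @param kind `"cancer"` or `"cart"`; division of CAR T-cells is an error.
#' @return The cell table with each flagged mother replaced by two daughters
#'   in phase G1.
#' @export
divide_cells <- function(cells, R_cell = 8.4, kind = "cancer") {
  if (kind == "cart" && any(cells$divide_now)) {
    abort("CAR T-cells never divide (divisions allowed is 0)")
  }
  idx <- which(cells$divide_now)
  if (length(idx) == 0) return(cells)
  mothers <- cells[idx, ]
  axis <- random_unit_axes(length(idx))
  off <- axis * R_cell / 2
  d1 <- d2 <- mothers
  d1$x <- mothers$x - off[, 1]; d1$y <- mothers$y - off[, 2]
  d1$z <- mothers$z - off[, 3]
  d2$x <- mothers$x + off[, 1]; d2$y <- mothers$y + off[, 2]
  d2$z <- mothers$z + off[, 3]
  d1$volume <- d2$volume <- mothers$volume / 2
  d1$phase <- d2$phase <- 1L
  d1$divide_now <- d2$divide_now <- FALSE
  dplyr::bind_rows(cells[-idx, ], d1, d2)
}

random_unit_axes <- function(n) {
  m <- matrix(rnorm(3 * n), n, 3)
  m / sqrt(rowSums(m^2))
}

#' Relax cell volumes toward their targets
#'
#' Each volume compartment relaxes exponentially toward its target,
#' integrated with the unconditionally stable implicit update
#' `V <- (V + r * dt * V_target) / (1 + r * dt)`.  Dead cells carry a zero
#' target, so their volume decreases monotonically until the removal
#' threshold.
#'
#' @param volume current volumes (um^3).
#' @param target target volumes (um^3); zero for dying cells.
#' @param rate relaxation rates (1/min).
#' @param dt time step (min).
#' @return Updated volumes.
#' @export
step_volume <- function(volume, target, rate, dt) {
  stopifnot(dt > 0, all(rate >= 0))
  out <- (volume + rate * dt * target) / (1 + rate * dt)
  if (any(out < 0)) abort("volume became negative")
  out
}

#' Stochastic necrosis from oxygen deprivation
#'
#' Below the necrosis oxygen threshold a live cell enters necrosis with
#' per-step probability `dt / tau_necrosis` (exponential waiting time with
#' mean `tau_necrosis`).  Necrosis is absorbing: necrotic cells stop cycling
#' and secreting and only shrink until removal.
#'
#' @param cells a data frame with a `death` column (`"none"`, `"apoptosis"`,
#'   `"necrosis"`).
#' @param o2 local oxygen per cell (mmHg); scalar recycled.
#' @param dt time step (min).
#' @param threshold necrosis oxygen threshold (mmHg).
#' @param tau mean waiting time to necrosis below the threshold (min).
#' @return `cells` with updated `death`.
#' @export
check_necrosis <- function(cells, o2, dt = 6, threshold = 5, tau = 360) {
  n <- nrow(cells)
  o2 <- rep_len(o2, n)
  eligible <- cells$death == "none" & o2 < threshold
  hit <- eligible & runif(n) < dt / tau
  cells$death[hit] <- "necrosis"
  cells
}
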