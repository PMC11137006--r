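#' Draw random migration directions
#'
#' By default replicates the source model's printed angle construction,
#' `d_r = (sin(phi) cos(theta), sin(phi) sin(theta), cos(phi))` with
#' `theta ~ U[0, pi]` and `phi ~ U[0, 2 pi]` — a unit vector that is not
#' area-uniform on the sphere (directions pile up near the poles of the
#' construction).  Set `uniform = TRUE` for area-uniform sampling.
#'
#' @param n number of directions.
#' @param uniform use area-uniform sampling instead of the printed scheme.
#' @return An n x 3 matrix of unit vectors.
#' @export
random_direction <- function(n, uniform = FALSE) {
  if (uniform) {
    return(random_unit_axes(n))
  }
  theta <- runif(n, 0, pi)
  phi <- runif(n, 0, 2 * pi)
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Resample the random component of migration directions
#'
#' Between consecutive mechanics steps each unattached CAR T-cell redraws its
#' random direction with probability `dt / t_per`, where `t_per` is the mean
#' persistence time; otherwise the direction is kept.
#'
#' @param d_r an n x 3 matrix of current random unit directions.
#' @param dt mechanics time step (min).
#' @param t_per persistence time (min); `Inf` disables resampling.
#' @param uniform passed to [random_direction()].
#' @return The (partially) resampled matrix, with attribute `resampled`
#'   giving the logical resample mask.
#' @export
resample_direction <- function(d_r, dt = 0.1, t_per = 10, uniform = FALSE) {
  n <- nrow(d_r)
  hit <- runif(n) < dt / t_per
  if (any(hit)) {
    d_r[hit, ] <- random_direction(sum(hit), uniform = uniform)
  }
  attr(d_r, "resampled") <- hit
  d_r
}

#' Chemotactic migration velocity
#'
#' The biased random walk blends the up-gradient direction `d` (unit vector
#' along the sampled immunostimulatory-factor gradient) with the random
#' direction `d_r`: `v = v_mot * (b d + (1 - b) d_r) / ||b d + (1 - b) d_r||`.
#' Bias `b = 1` gives deterministic motion up the gradient, `b = 0` a
#' Brownian-like walk along `d_r`; the speed is always `v_mot` (if the blend
#' cancels exactly, the cell falls back to `d_r`).  Attached cells have zero
#' migration velocity.
#'
#' @param d n x 3 matrix of unit gradient directions.
#' @param d_r n x 3 matrix of unit random directions.
#' @param b migration bias in \[0, 1\].
#' @param v_mot migration speed (um/min).
#' @param attached logical per cell; attached cells get (0, 0, 0).
#' @return An n x 3 matrix of migration velocities (um/min).
#' @export
migration_velocity <- function(d, d_r, b = 0.5, v_mot = 2, attached = FALSE) {
  stopifnot(b >= 0, b <= 1)
  blend <- b * d + (1 - b) * d_r
  nrm <- sqrt(rowSums(blend^2))
  degenerate <- nrm < 1e-12
  nrm[degenerate] <- 1
  v <- v_mot * blend / nrm
  if (any(degenerate)) v[degenerate, ] <- v_mot * d_r[degenerate, ]
  v[rep_len(attached, nrow(d)), ] <- 0
  v
}

#' Attempt to form an adhesion to a nearby cancer cell
#'
#' A free CAR T-cell in contact range forms an adhesion with probability
#' `r_adh * dt` per step.  Candidates must lie within the maximum adhesion
#' distance `R_LA` and, in antigen-specific mode, present oncoprotein at or
#' above the recognition threshold (Type 4 cells can never be bound).  The
#' adhesion goes to the nearest eligible candidate, ties broken by lowest
#' index.  On adhesion the T-cell switches off its motility and the target
#' freezes its cycling.
#'
#' @param tcell a list/row with `x`, `y`, `z`.
#' @param targets a data frame of cancer cells with `x`, `y`, `z`, `o` and
#'   optionally `death` (only `"none"` rows are eligible).
#' @param dt mechanics time step (min).
#' @param r_adh adhesion rate (1/min).
#' @param R_LA maximum adhesion distance (um).
#' @param mode recognition mode.
#' @param threshold recognition threshold on `o`.
#' @return The integer row index of the adhered target, or `NA_integer_`.
#' @export
attempt_adhesion <- function(tcell, targets, dt = 0.1, r_adh = 0.2,
                             R_LA = 18,
                             mode = c("antigen_specific", "multi_antigen"),
                             threshold = 0.5) {
  mode <- match.arg(mode)
  if (nrow(targets) == 0) return(NA_integer_)
  alive <- rep_len(col_or(targets, "death", "none"), nrow(targets)) == "none"
  eligible <- alive & (mode == "multi_antigen" | targets$o >= threshold)
  d <- sqrt((targets$x - tcell$x)^2 + (targets$y - tcell$y)^2 +
              (targets$z - tcell$z)^2)
  eligible <- eligible & d <= R_LA
  if (!any(eligible)) return(NA_integer_)
  if (runif(1) >= r_adh * dt) return(NA_integer_)
  cand <- which(eligible)
  cand[order(d[cand], cand)][1]
}

#' Attempt to kill an attached target
#'
#' While attached, the T-cell attempts to induce apoptosis once per step with
#' probability `min(1, r_kill * dt * immunogenicity(o))`; on success the
#' target enters apoptosis, the kill is attributed to this T-cell, and the
#' T-cell detaches to resume its chemotactic search.  If the attachment clock
#' exceeds the maximum attachment lifetime `t_attach`, the T-cell detaches
#' without inducing apoptosis.  A target that is already dead yields an
#' immediate detach with no kill attributed.
#'
#' @param o target oncoprotein (vectorised over attachments).
#' @param clock attachment clock after this step (min).
#' @param dt mechanics time step (min).
#' @param r_kill kill rate (1/min).
#' @param t_attach maximum attachment lifetime (min).
#' @param mode recognition mode.
#' @param threshold recognition threshold.
#' @param target_dead logical; target already dead.
#' @return Character vector over attachments: `"kill"`, `"detach"` or
#'   `"stay"`.
#' @export
attempt_kill <- function(o, clock, dt = 0.1, r_kill = 0.06, t_attach = 60,
                         mode = c("antigen_specific", "multi_antigen"),
                         threshold = 0.5, target_dead = FALSE) {
  mode <- match.arg(mode)
  n <- max(length(o), length(clock))
  o <- rep_len(o, n)
  clock <- rep_len(clock, n)
  target_dead <- rep_len(target_dead, n)
  p <- pmin(1, r_kill * dt * immunogenicity(o, mode, threshold))
  killed <- p > 0 & runif(n) < p
  out <- ifelse(target_dead, "detach",
                ifelse(killed, "kill",
                       ifelse(clock >= t_attach, "detach", "stay")))
  out
}

#' Draw stochastic CAR T-cell lifespans
#'
#' Exhaustion times are drawn once per cell at dose time from a normal
#' distribution truncated at zero (mean 10 days, sd 5 days by default);
#' a cell is removed from the simulation when its age exceeds its lifespan.
#' In long-term persistence mode the lifespan is infinite and cells last the
#' entire simulation.
#'
#' @param n number of draws.
#' @param mean,sd moments in days.
#' @param long_term if `TRUE`, return `Inf` lifespans.
#' @return Lifespans in days.
#' @export
draw_lifespan <- function(n, mean = 10, sd = 5, long_term = FALSE) {
  if (long_term) return(rep(Inf, n))
  out <- numeric(0)
  while (length(out) < n) {
    draw <- rnorm(n - length(out) + 16L, mean, sd)
    out <- c(out, draw[draw > 0])
  }
  out[seq_len(n)]
}

#' Mean of the zero-truncated lifespan distribution
#'
#' Closed-form mean of a normal(mean, sd) truncated to (0, Inf):
#' `mean + sd * dnorm(a) / (1 - pnorm(a))` with `a = -mean / sd`.
#' Used as the analytic oracle for exhaustion-age statistics.
#'
#' @param mean,sd moments of the parent normal, in days.
#' @return The truncated mean in days.
#' @export
truncated_lifespan_mean <- function(mean = 10, sd = 5) {
  a <- -mean / sd
  mean + sd * dnorm(a) / (1 - pnorm(a))
}

#' Check CAR T-cell exhaustion
#'
#' @param age current ages (days).
#' @param lifespan lifespans from [draw_lifespan()] (days).
#' @return Logical vector: `TRUE` while the cell is still alive.
#' @export
check_exhaustion <- function(age, lifespan) {
  age <= lifespan
}

#' Place a CAR T-cell dose around an organoid
#'
#' Dosed T-cells are placed uniformly at random in cell-free space: positions
#' are drawn uniformly in the domain and accepted when they fall outside the
#' organoid's bounding sphere (about its live-cell centre of mass) plus one
#' cell diameter, reproducing arrival at the organoid's exposed surface
#' without privileging a direction.
#'
#' @param n number of T-cells to place.
#' @param cancer a data frame of cancer cells with `x`, `y`, `z`.
#' @param domain domain edge length (um).
#' @param R_cell cell radius (um).
#' @return An n x 3 matrix of positions.
#' @export
place_dose <- function(n, cancer, domain = 1000, R_cell = 8.4) {
  com <- c(mean(cancer$x), mean(cancer$y), mean(cancer$z))
  rb <- sqrt(max((cancer$x - com[1])^2 + (cancer$y - com[2])^2 +
                   (cancer$z - com[3])^2))
  margin <- rb + 2 * R_cell
  out <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    for (tries in 1:2000) {
      p <- runif(3, 0, domain)
      if (sqrt(sum((p - com)^2)) > margin) break
    }
    out[i, ] <- p
  }
  colnames(out) <- c("x", "y", "z")
  out
}
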