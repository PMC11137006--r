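#' Mechanics parameters
#'
#' Off-lattice cell mechanics constants.  Forces are expressed directly as
#' velocities (um/min): the overdamped limit with a unit drag coefficient
#' absorbed into the constants.  Repulsion (an elastic resistance to
#' deformation) acts below contact distance `Ra + Rb` with strength
#' `sqrt(Ca * Cb) * (1 - d / (Ra + Rb))^2`; adhesion acts in the ring between
#' contact and the maximum adhesion distance
#' `R_A = adhesion_distance_scale * (Ra + Rb)` with strength
#' `adhesion_strength * (1 - d / R_A)^2`.
#'
#' @param repulsion repulsion constant C_ccr in units of `nu` (10 for cancer
#'   cells, 5 for CAR T-cells).
#' @param adhesion adhesion constant C_cca (um/min).
#' @param adhesion_distance_scale max adhesion distance over contact distance.
#' @param nu velocity scale of the force constants (um/min).
#' @param bin_size mechanics neighbour-list voxel edge (um).
#' @param dt mechanics time step (min).
#' @param t_v_steps neighbour-list refresh interval, in mechanics steps.
#' @return A named list of class `mechanics_params`.
#' @export
mechanics_params <- function(repulsion = 10, adhesion = 0.4,
                             adhesion_distance_scale = 1.25, nu = 1,
                             bin_size = 30, dt = 0.1, t_v_steps = 20) {
  stopifnot(repulsion >= 0, adhesion >= 0, adhesion_distance_scale > 1,
            nu >= 0, bin_size > 0, dt > 0)
  structure(
    list(repulsion = repulsion, adhesion = adhesion,
         adhesion_distance_scale = adhesion_distance_scale, nu = nu,
         bin_size = bin_size, dt = dt, t_v_steps = t_v_steps),
    class = "mechanics_params"
  )
}

#' Pairwise interaction velocity
#'
#' Velocity contribution on agent `a` from agent `b`: repulsive (away from
#' `b`) when the cells overlap, adhesive (toward `b`) in the ring between
#' contact and the maximum adhesion distance, zero beyond it, and exactly
#' antisymmetric between the pair.  Coincident centres are pushed apart along
#' a random (seed-deterministic) axis.
#'
#' @param a,b rows of an agent table, or lists, with `x`, `y`, `z`, `radius`,
#'   and optionally `repulsion` (defaults to `params$repulsion`).
#' @param params a [mechanics_params()] object.
#' @return Length-3 numeric velocity contribution on `a` (um/min).
#' @export
pairwise_force <- function(a, b, params = mechanics_params()) {
  ca <- col_or(a, "repulsion", params$repulsion) * params$nu
  cb <- col_or(b, "repulsion", params$repulsion) * params$nu
  cpp_pair_force(c(a$x, a$y, a$z), c(b$x, b$y, b$z), a$radius, b$radius,
                 ca, cb, params$adhesion * params$nu,
                 params$adhesion_distance_scale)
}

#' Advance agent positions by one overdamped step
#'
#' Each agent's velocity is the sum of its pairwise interaction velocities
#' plus an optional motility term; positions advance by forward Euler and are
#' clamped to the domain.  Frozen agents (attached immune cells) receive no
#' motility, only interaction forces.
#'
#' @param agents a data frame with columns `x`, `y`, `z`, `radius` and
#'   optionally `repulsion`.
#' @param params a [mechanics_params()] object.
#' @param dt time step (min); defaults to `params$dt`.
#' @param domain domain edge length(s), um.
#' @param motility n x 3 matrix of motility velocities (um/min); default zero.
#' @param frozen logical vector: agents whose motility is switched off.
#' @return The agent table with updated positions and velocity columns
#'   `vx`, `vy`, `vz`; attributes `clamped` (count of boundary clamp events)
#'   and `max_displacement` (um) carry step diagnostics.  A displacement
#'   exceeding one cell radius raises a time-step warning.
#' @export
update_motion <- function(agents, params = mechanics_params(),
                          dt = params$dt, domain = 1000,
                          motility = NULL, frozen = NULL) {
  n <- nrow(agents)
  if (n == 0) return(agents)
  if (is.null(motility)) motility <- matrix(0, n, 3)
  if (is.null(frozen)) frozen <- rep(FALSE, n)
  rep_vec <- rep_len(col_or(agents, "repulsion", params$repulsion), n) *
    params$nu
  domain <- rep_len(domain, 3)
  res <- cpp_update_motion(
    as.matrix(agents[, c("x", "y", "z")]), agents$radius, rep_vec,
    params$adhesion * params$nu, params$adhesion_distance_scale,
    motility, frozen, dt, domain, params$bin_size
  )
  if (res$max_displacement > max(agents$radius)) {
    warn(sprintf(
      "per-step displacement %.2f um exceeds one cell radius; the mechanics time step is too large",
      res$max_displacement
    ))
  }
  agents$x <- res$position[, 1]
  agents$y <- res$position[, 2]
  agents$z <- res$position[, 3]
  agents$vx <- res$velocity[, 1]
  agents$vy <- res$velocity[, 2]
  agents$vz <- res$velocity[, 3]
  attr(agents, "clamped") <- res$clamped
  attr(agents, "max_displacement") <- res$max_displacement
  agents
}

#' Find agents within a radius of query points
#'
#' Voxelised neighbour search (closed-ball convention: an agent exactly at
#' the query radius is included).  The search widens automatically when the
#' radius exceeds the bin edge.
#'
#' @param agents a data frame with columns `x`, `y`, `z`.
#' @param query an m x 3 matrix (or length-3 vector) of query positions.
#' @param radius search radius (um).
#' @param params a [mechanics_params()] object (for the bin edge).
#' @param domain domain edge length(s), um.
#' @return A list of integer vectors of agent row indices, one per query.
#' @export
find_neighbors <- function(agents, query, radius,
                           params = mechanics_params(), domain = 1000) {
  query <- rbind3(query)
  if (nrow(agents) == 0) {
    return(rep(list(integer(0)), nrow(query)))
  }
  cpp_neighbors(as.matrix(agents[, c("x", "y", "z")]), query, radius,
                params$bin_size, rep_len(domain, 3))
}
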