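#' Create a voxelised substrate grid
#'
#' Discretises a cubic domain into cubic voxels, each storing one
#' concentration per diffusing substrate.  By default two substrates are
#' carried: oxygen (mmHg) and the immunostimulatory factor secreted by cancer
#' cells (arbitrary units).  Positions are in um with the origin at the domain
#' corner; a position belongs to the voxel `floor(position / voxel_size)`
#' (half-open intervals, 0-based indices internally, 1-based in R).
#'
#' @param extent domain edge length per axis (um); must be an integer
#'   multiple of `voxel_size`.
#' @param voxel_size voxel edge length (um).
#' @param substrates a data frame with columns `name`, `diffusion`
#'   (um^2/min), `decay` (1/min), `init` (initial uniform value), and
#'   `saturation` (secretion target).  Defaults to the oxygen +
#'   immunostimulatory-factor pair.
#' @return An object of class `substrate_grid`.
#' @examples
#' grid <- substrate_grid(extent = 100, voxel_size = 20)
#' dim(grid$fields$oxygen)
#' @export
substrate_grid <- function(extent = 1000, voxel_size = 20,
                           substrates = default_substrates()) {
  n <- extent / voxel_size
  if (abs(n - round(n)) > 1e-8) {
    abort("extent must be an integer multiple of voxel_size")
  }
  n <- as.integer(round(n))
  fields <- purrr::map(
    setNames(substrates$init, substrates$name),
    ~ array(.x, dim = c(n, n, n))
  )
  structure(
    list(
      extent = extent, voxel_size = voxel_size, dims = c(n, n, n),
      params = tibble::as_tibble(substrates),
      fields = fields,
      dirichlet = tibble::tibble(substrate = character(), voxel = integer(),
                                 value = double())
    ),
    class = "substrate_grid"
  )
}

#' @rdname substrate_grid
#' @export
default_substrates <- function() {
  tibble::tibble(
    name = c("oxygen", "immunostimulatory"),
    diffusion = c(1e5, 1e3),
    decay = c(0.1, 0.016),
    init = c(38, 0),
    saturation = c(38, 1)
  )
}

#' @export
print.substrate_grid <- function(x, ...) {
  cat(sprintf("<substrate_grid> %g um domain, %d^3 voxels of %g um\n",
              x$extent, x$dims[1], x$voxel_size))
  print(x$params)
  invisible(x)
}

#' Convert positions to voxel indices
#'
#' @param grid a `substrate_grid`.
#' @param position an n x 3 matrix (or length-3 vector) of positions in um.
#' @return Integer vector of 1-based linear voxel indices.
#' @export
voxel_index <- function(grid, position) {
  position <- rbind3(position)
  check_in_domain(grid, position)
  ijk <- pmin(floor(position / grid$voxel_size), grid$dims[1] - 1)
  as.integer(1 + ijk[, 1] + grid$dims[1] * (ijk[, 2] + grid$dims[2] * ijk[, 3]))
}

#' Clamp voxels to fixed substrate values (Dirichlet nodes)
#'
#' Dirichlet nodes act as continuous sources: their concentration is
#' overwritten with the clamped value immediately after every diffusion step.
#'
#' @param grid a `substrate_grid`.
#' @param substrate substrate name.
#' @param voxel 1-based linear voxel indices (see [voxel_index()]).
#' @param value clamped value (recycled).
#' @return The modified grid.
#' @export
set_dirichlet <- function(grid, substrate, voxel, value) {
  stopifnot(substrate %in% grid$params$name)
  new <- tibble::tibble(substrate = substrate, voxel = as.integer(voxel),
                        value = rep_len(value, length(voxel)))
  grid$dirichlet <- dplyr::bind_rows(grid$dirichlet, new) |>
    dplyr::distinct(.data$substrate, .data$voxel, .keep_all = TRUE)
  for (r in seq_len(nrow(new))) {
    grid$fields[[substrate]][new$voxel[r]] <- new$value[r]
  }
  grid
}

#' Advance the reaction-diffusion system by one implicit step
#'
#' Applies, per substrate, an implicit decay step followed by
#' locally-one-dimensional (LOD) implicit diffusion with tridiagonal solves
#' along each axis.  Boundary conditions are zero-flux on the domain faces;
#' Dirichlet nodes are re-clamped after the step.  The scheme is
#' unconditionally stable, conserves mass exactly in the decay-free,
#' source-free case, and for D = 0 reduces to the closed form
#' `c / (1 + decay * dt)`.
#'
#' @param grid a `substrate_grid`.
#' @param dt time step in minutes.
#' @return The advanced grid.
#' @export
step_diffusion <- function(grid, dt) {
  stopifnot(dt > 0)
  for (s in seq_len(nrow(grid$params))) {
    nm <- grid$params$name[s]
    dn <- dplyr::filter(grid$dirichlet, .data$substrate == nm)
    out <- cpp_lod_step(
      as.numeric(grid$fields[[nm]]), as.integer(grid$dims), grid$voxel_size,
      grid$params$diffusion[s], grid$params$decay[s], dt,
      as.integer(dn$voxel - 1L), dn$value
    )
    grid$fields[[nm]] <- array(out, dim = grid$dims)
  }
  grid
}

#' Apply per-cell secretion and uptake to the microenvironment
#'
#' Each agent exchanges with its containing voxel only (the voxel edge is
#' about one cell diameter).  Secretion moves the voxel concentration toward
#' the substrate's saturation value and uptake is a proportional sink; both
#' use a rate-limited implicit update scaled by the cell-to-voxel volume
#' ratio, so uptake can never drive a concentration negative.
#'
#' @param grid a `substrate_grid`.
#' @param agents a data frame with columns `x`, `y`, `z`, `volume` (um^3) and
#'   per-substrate rate columns named `secretion_<name>` and `uptake_<name>`
#'   (1/min); absent rate columns default to zero.
#' @param dt time step in minutes.
#' @return The updated grid.
#' @export
apply_cell_exchange <- function(grid, agents, dt) {
  stopifnot(dt > 0)
  pos <- as.matrix(agents[, c("x", "y", "z")])
  check_in_domain(grid, pos)
  n <- nrow(agents)
  vol <- rep_len(col_or(agents, "volume", cell_volume(8.4)), n)
  for (s in seq_len(nrow(grid$params))) {
    nm <- grid$params$name[s]
    sec <- rep_len(col_or(agents, paste0("secretion_", nm), 0), n)
    upt <- rep_len(col_or(agents, paste0("uptake_", nm), 0), n)
    out <- cpp_apply_exchange(
      as.numeric(grid$fields[[nm]]), as.integer(grid$dims), grid$voxel_size,
      pos, sec, upt, grid$params$saturation[s], vol, dt
    )
    grid$fields[[nm]] <- array(out, dim = grid$dims)
  }
  grid
}

#' Sample substrate values at positions
#'
#' @param grid a `substrate_grid`.
#' @param position an n x 3 matrix (or length-3 vector) of positions (um).
#' @param substrate substrate name(s); default all.
#' @return A tibble with one row per position and one column per substrate.
#' @export
sample_substrate <- function(grid, position, substrate = grid$params$name) {
  position <- rbind3(position)
  check_in_domain(grid, position)
  out <- purrr::map(
    setNames(substrate, substrate),
    ~ cpp_sample_field(as.numeric(grid$fields[[.x]]), as.integer(grid$dims),
                       grid$voxel_size, position)
  )
  tibble::as_tibble(out)
}

#' Sample a substrate gradient at positions
#'
#' Central finite differences on voxel centres, one-sided at domain faces;
#' exact for fields linear in the voxel-centre coordinates.
#'
#' @param grid a `substrate_grid`.
#' @param position an n x 3 matrix (or length-3 vector) of positions (um).
#' @param substrate a single substrate name.
#' @return An n x 3 matrix of gradient components (units per um).
#' @export
sample_gradient <- function(grid, position, substrate = "immunostimulatory") {
  position <- rbind3(position)
  check_in_domain(grid, position)
  stopifnot(length(substrate) == 1, substrate %in% grid$params$name)
  g <- cpp_sample_gradient(as.numeric(grid$fields[[substrate]]),
                           as.integer(grid$dims), grid$voxel_size, position)
  colnames(g) <- c("x", "y", "z")
  g
}

#' Total substrate mass on the grid
#'
#' @param grid a `substrate_grid`.
#' @param substrate substrate name.
#' @return Sum of concentration times voxel volume.
#' @export
total_mass <- function(grid, substrate) {
  sum(grid$fields[[substrate]]) * grid$voxel_size^3
}

#' Export a substrate field as a voxel table
#'
#' @param grid a `substrate_grid`.
#' @param substrate substrate name.
#' @return A tibble with voxel index, voxel-centre coordinates and value.
#' @export
field_table <- function(grid, substrate) {
  n <- grid$dims[1]
  idx <- seq_len(n^3)
  ijk <- arrayInd(idx, grid$dims)
  tibble::tibble(
    voxel = idx,
    x = (ijk[, 1] - 0.5) * grid$voxel_size,
    y = (ijk[, 2] - 0.5) * grid$voxel_size,
    z = (ijk[, 3] - 0.5) * grid$voxel_size,
    value = as.numeric(grid$fields[[substrate]])
  )
}

cell_volume <- function(radius) 4 / 3 * pi * radius^3

# column lookup that tolerates absent columns in tibbles and lists
col_or <- function(d, nm, default) {
  v <- tryCatch(d[[nm]], error = function(e) NULL)
  if (is.null(v)) default else v
}

rbind3 <- function(position) {
  if (is.null(dim(position))) position <- matrix(position, ncol = 3)
  storage.mode(position) <- "double"
  position
}

check_in_domain <- function(grid, position) {
  bad <- position[, 1] < 0 | position[, 2] < 0 | position[, 3] < 0 |
    position[, 1] >= grid$extent | position[, 2] >= grid$extent |
    position[, 3] >= grid$extent
  if (any(bad)) {
    i <- which(bad)[1]
    abort(sprintf("position (%g, %g, %g) lies outside the domain [0, %g)^3",
                  position[i, 1], position[i, 2], position[i, 3], grid$extent))
  }
  invisible(TRUE)
}
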