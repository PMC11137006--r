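# Shared fixtures for the suite: small grids and short simulation configs.

# a single-substrate grid with chosen physics (decay-free tracer by default)
tracer_grid <- function(extent = 100, voxel = 20, D = 1e3, decay = 0,
                        init = 0, saturation = 1, name = "tracer") {
  substrate_grid(
    extent = extent, voxel_size = voxel,
    substrates = tibble::tibble(name = name, diffusion = D, decay = decay,
                                init = init, saturation = saturation)
  )
}

# explicit forward-Euler reference for 3D diffusion + decay with zero-flux
# boundaries; the independent fine-step oracle for the implicit LOD solver
explicit_diffusion_oracle <- function(field, D, decay, dt, dx, steps) {
  n <- dim(field)[1]
  idx <- function(i) pmin(pmax(i, 1), n)   # zero-flux ghost cells
  for (s in seq_len(steps)) {
    lap <- (field[idx(0:(n - 1)), , ] + field[idx(2:(n + 1)), , ] +
              field[, idx(0:(n - 1)), ] + field[, idx(2:(n + 1)), ] +
              field[, , idx(0:(n - 1))] + field[, , idx(2:(n + 1))] -
              6 * field) / dx^2
    field <- field + dt * (D * lap - decay * field)
  }
  field
}

# smoke-scale treated configuration
smoke_config <- function(..., n_cells = 120, days = 1.5, seed = 101) {
  desk_config(n_cells = n_cells, days = days, seed = seed, t_save = 720, ...)
}
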