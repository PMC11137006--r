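test_that("diffusing a uniform field leaves it unchanged", {
  g <- tracer_grid(extent = 100, D = 1e3, decay = 0, init = 5)
  g2 <- step_diffusion(g, dt = 0.01)
  expect_equal(g2$fields$tracer, g$fields$tracer, tolerance = 1e-14)
})

test_that("pure decay matches the implicit closed form", {
  g <- tracer_grid(extent = 100, D = 0, decay = 0.1, init = 1)
  g2 <- step_diffusion(g, dt = 0.01)
  expect_equal(as.numeric(g2$fields$tracer),
               rep(1 / (1 + 0.1 * 0.01), 125), tolerance = 1e-12)
})

test_that("implicit LOD solver agrees with a fine-step explicit oracle", {
  set.seed(1)
  g <- tracer_grid(extent = 100, D = 1e3, decay = 0, init = 0)
  hot <- c(3, 3, 3)
  g$fields$tracer[hot[1], hot[2], hot[3]] <- 1
  ref <- explicit_diffusion_oracle(g$fields$tracer, D = 1e3, decay = 0,
                                   dt = 0.01 / 100, dx = 20,
                                   steps = 200 * 100)
  g100 <- g
  for (s in 1:200) g100 <- step_diffusion(g100, dt = 0.01)
  hot_val <- g100$fields$tracer[hot[1], hot[2], hot[3]]
  expect_lt(abs(hot_val - ref[hot[1], hot[2], hot[3]]) /
              ref[hot[1], hot[2], hot[3]], 0.01)
})

test_that("halving the step halves the discrepancy against the fine oracle", {
  g0 <- tracer_grid(extent = 100, D = 1e3, decay = 0.01, init = 0)
  g0$fields$tracer[3, 3, 3] <- 1
  ref <- explicit_diffusion_oracle(g0$fields$tracer, D = 1e3, decay = 0.01,
                                   dt = 1 / 2000, dx = 20, steps = 2000)
  err_at <- function(dt) {
    g <- g0
    for (s in seq_len(round(1 / dt))) g <- step_diffusion(g, dt)
    max(abs(g$fields$tracer - ref))
  }
  e1 <- err_at(0.05)
  e2 <- err_at(0.025)
  expect_gt(e1 / e2, 1.5)
  expect_lt(e1 / e2, 3)
})

test_that("mass is conserved without decay, sources or Dirichlet nodes", {
  set.seed(42)
  g <- tracer_grid(extent = 100, D = 1e4, decay = 0, init = 0)
  g$fields$tracer <- array(runif(125), dim = c(5, 5, 5))
  m0 <- total_mass(g, "tracer")
  for (s in 1:1000) g <- step_diffusion(g, dt = 0.01)
  expect_lt(abs(total_mass(g, "tracer") - m0) / m0, 1e-10)
  expect_true(all(g$fields$tracer >= 0))
})

test_that("Dirichlet nodes hold their clamped value after every step", {
  g <- substrate_grid(extent = 100, voxel_size = 20)
  centre <- voxel_index(g, c(50, 50, 50))
  g <- set_dirichlet(g, "oxygen", centre, 70)
  for (s in 1:5) {
    g <- step_diffusion(g, dt = 0.01)
    expect_identical(g$fields$oxygen[centre], 70)
  }
})

test_that("secretion + decay in a sealed voxel reaches the analytic fixed point", {
  g <- tracer_grid(extent = 20, voxel = 20, D = 0, decay = 0.02, init = 0,
                   saturation = 1)
  agent <- tibble::tibble(x = 10, y = 10, z = 10,
                          volume = 4 / 3 * pi * 8.4^3, secretion_tracer = 10,
                          uptake_tracer = 0)
  dt <- 0.01
  rho <- agent$volume / 20^3
  a <- dt * rho * 10
  # fixed point of c -> ((c / (1 + decay dt)) + a sat) / (1 + a)
  c_star <- a * 1 / (1 + a - 1 / (1 + 0.02 * dt))
  for (s in 1:20000) {
    g <- step_diffusion(g, dt)
    g <- apply_cell_exchange(g, agent, dt)
  }
  expect_equal(as.numeric(g$fields$tracer), c_star, tolerance = 1e-8)
})

test_that("cell exchange follows the implicit closed forms", {
  g <- tracer_grid(extent = 100, voxel = 20, D = 0, decay = 0, init = 2)
  vol <- 4 / 3 * pi * 8.4^3
  rho <- vol / 20^3
  # zero rates leave the state unchanged
  idle <- tibble::tibble(x = 50, y = 50, z = 50, volume = vol,
                         secretion_tracer = 0, uptake_tracer = 0)
  expect_equal(apply_cell_exchange(g, idle, 0.01)$fields$tracer,
               g$fields$tracer)
  # pure uptake: c = c0 / (1 + U dt rho), decreasing and positive
  sink <- tibble::tibble(x = 50, y = 50, z = 50, volume = vol,
                         secretion_tracer = 0, uptake_tracer = 10)
  g2 <- apply_cell_exchange(g, sink, 0.01)
  v <- voxel_index(g, c(50, 50, 50))
  expect_equal(g2$fields$tracer[v], 2 / (1 + 10 * 0.01 * rho),
               tolerance = 1e-12)
  expect_lt(g2$fields$tracer[v], 2)
  expect_gt(g2$fields$tracer[v], 0)
  # two secreting agents equal sequential one-at-a-time application
  two <- tibble::tibble(x = c(50, 50), y = c(50, 50), z = c(50, 50),
                        volume = vol, secretion_tracer = 10,
                        uptake_tracer = 0)
  g_both <- apply_cell_exchange(g, two, 0.01)
  g_seq <- apply_cell_exchange(apply_cell_exchange(g, two[1, ], 0.01),
                               two[2, ], 0.01)
  expect_equal(g_both$fields$tracer[v], g_seq$fields$tracer[v],
               tolerance = 1e-12)
  # agents outside the domain are rejected with the position in the message
  outside <- tibble::tibble(x = 150, y = 50, z = 50, volume = vol,
                            secretion_tracer = 1, uptake_tracer = 0)
  expect_error(apply_cell_exchange(g, outside, 0.01), "150")
})

test_that("value and gradient sampling are exact for linear fields", {
  g <- tracer_grid(extent = 100, voxel = 20, D = 0, decay = 0)
  a <- 0.3
  centres <- (seq_len(5) - 0.5) * 20
  for (i in 1:5) g$fields$tracer[i, , ] <- a * centres[i]
  # uniform-in-yz field: value equals the containing voxel's concentration
  expect_equal(sample_substrate(g, c(50, 50, 50))$tracer, a * 50)
  expect_equal(sample_substrate(g, c(41, 50, 50))$tracer, a * 50)
  grad <- sample_gradient(g, rbind(c(50, 50, 50), c(10, 50, 50),
                                   c(95, 50, 50)), "tracer")
  expect_equal(unname(grad[, "x"]), rep(a, 3), tolerance = 1e-12)
  expect_equal(unname(grad[, "y"]), rep(0, 3))
  expect_equal(unname(grad[, "z"]), rep(0, 3))
  # uniform field: zero gradient
  gu <- tracer_grid(extent = 100, voxel = 20, init = 7)
  expect_equal(unname(sample_gradient(gu, c(50, 50, 50), "tracer")[1, ]),
               c(0, 0, 0))
  expect_error(sample_substrate(g, c(101, 50, 50)), "outside")
  expect_error(sample_gradient(g, c(-1, 50, 50), "tracer"), "outside")
})

test_that("voxel indexing round-trips positions to their containing voxel", {
  g <- substrate_grid(extent = 100, voxel_size = 20)
  pos <- rbind(c(0, 0, 0), c(19.99, 0, 0), c(20, 0, 0), c(99.9, 99.9, 99.9))
  idx <- voxel_index(g, pos)
  expect_identical(idx, c(1L, 1L, 2L, 125L))
  # centre of every voxel maps back to that voxel
  ft <- field_table(g, "oxygen")
  expect_identical(voxel_index(g, as.matrix(ft[, c("x", "y", "z")])),
                   ft$voxel)
})
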