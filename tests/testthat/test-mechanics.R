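agent <- function(x, y, z, radius = 8.4, repulsion = 10) {
  list(x = x, y = y, z = z, radius = radius, repulsion = repulsion)
}

test_that("pairwise force is zero beyond the interaction range", {
  a <- agent(50, 50, 50)
  b <- agent(50 + 3 * 8.4, 50, 50)   # beyond 1.25 * (Ra + Rb) = 21 um
  expect_identical(pairwise_force(a, b), c(0, 0, 0))
})

test_that("overlap repulsion matches the contact-model formula", {
  a <- agent(50, 50, 50)
  b <- agent(50 + 8.4, 50, 50)       # separation 1 cell radius: strong overlap
  f <- pairwise_force(a, b)
  expect_equal(f, c(-10 * (1 - 8.4 / 16.8)^2, 0, 0), tolerance = 1e-12)
  # adhesive ring: between contact (16.8) and max adhesion distance (21)
  b2 <- agent(50 + 18.48, 50, 50)
  f2 <- pairwise_force(a, b2)
  expect_equal(f2, c(0.4 * (1 - 18.48 / 21)^2, 0, 0), tolerance = 1e-12)
})

test_that("pairwise forces are antisymmetric for random pairs", {
  set.seed(7)
  for (i in 1:100) {
    a <- agent(runif(1, 40, 60), runif(1, 40, 60), runif(1, 40, 60),
               radius = runif(1, 6, 10), repulsion = sample(c(5, 10), 1))
    b <- agent(a$x + runif(1, -15, 15), a$y + runif(1, -15, 15),
               a$z + runif(1, -15, 15), radius = runif(1, 6, 10),
               repulsion = sample(c(5, 10), 1))
    expect_equal(pairwise_force(a, b), -pairwise_force(b, a),
                 tolerance = 1e-12)
  }
})

test_that("an isolated, non-motile cell does not move", {
  cells <- tibble::tibble(x = 150, y = 150, z = 150, radius = 8.4)
  out <- update_motion(cells, domain = 300)
  expect_identical(c(out$x, out$y, out$z), c(150, 150, 150))
})

test_that("an overlapping pair relaxes monotonically, matching a fine-step oracle", {
  start <- tibble::tibble(x = c(150, 150 + 8.4), y = 150, z = 150,
                          radius = 8.4)
  run <- function(dt, t_end = 10) {
    cells <- start
    seps <- numeric(0)
    for (s in seq_len(round(t_end / dt))) {
      cells <- update_motion(cells, dt = dt, domain = 300)
      seps <- c(seps, abs(cells$x[2] - cells$x[1]))
    }
    list(cells = cells, seps = seps)
  }
  coarse <- run(0.1)
  fine <- run(0.001)
  expect_true(all(diff(coarse$seps) >= -1e-12))   # separation non-decreasing
  sep_c <- abs(coarse$cells$x[2] - coarse$cells$x[1])
  sep_f <- abs(fine$cells$x[2] - fine$cells$x[1])
  expect_lt(abs(sep_c - sep_f) / sep_f, 0.01)
  # midpoint of an equal-parameter pair is stationary (momentum-free contract)
  expect_equal((coarse$cells$x[1] + coarse$cells$x[2]) / 2, 150 + 4.2,
               tolerance = 1e-9)
  expect_equal(coarse$cells$y, c(150, 150))
})

test_that("frozen agents receive no motility but still feel forces", {
  cells <- tibble::tibble(x = c(150, 160), y = 150, z = 150, radius = 8.4)
  motility <- rbind(c(2, 0, 0), c(0, 0, 0))
  frozen <- c(TRUE, FALSE)
  out <- update_motion(cells, dt = 0.1, domain = 300, motility = motility,
                       frozen = frozen)
  # overlap pushes agent 1 left despite its (suppressed) rightward motility
  expect_lt(out$x[1], 150)
  # isolated frozen agent with motility does not move at all
  solo <- tibble::tibble(x = 150, y = 150, z = 150, radius = 8.4)
  out2 <- update_motion(solo, dt = 0.1, domain = 300,
                        motility = rbind(c(2, 0, 0)), frozen = TRUE)
  expect_identical(out2$x, 150)
})

test_that("positions are clamped at the domain faces and clamps are counted", {
  cells <- tibble::tibble(x = 0.05, y = 150, z = 150, radius = 8.4)
  out <- update_motion(cells, dt = 0.1, domain = 300,
                       motility = rbind(c(-10, 0, 0)))
  expect_identical(out$x, 0)
  expect_gte(attr(out, "clamped"), 1)
})

test_that("neighbour search matches brute force and uses a closed ball", {
  set.seed(11)
  agents <- tibble::tibble(x = runif(200, 0, 300), y = runif(200, 0, 300),
                           z = runif(200, 0, 300))
  queries <- cbind(runif(50, 0, 300), runif(50, 0, 300), runif(50, 0, 300))
  r <- 25
  got <- find_neighbors(agents, queries, r, domain = 300)
  for (q in seq_len(50)) {
    d <- sqrt((agents$x - queries[q, 1])^2 + (agents$y - queries[q, 2])^2 +
                (agents$z - queries[q, 3])^2)
    expect_identical(sort(got[[q]]), which(d <= r))
  }
  # empty population
  none <- find_neighbors(agents[0, ], c(10, 10, 10), 30, domain = 300)
  expect_identical(none[[1]], integer(0))
  # agent exactly at the radius is included
  one <- tibble::tibble(x = 60, y = 50, z = 50)
  expect_identical(find_neighbors(one, c(50, 50, 50), 10, domain = 300)[[1]],
                   1L)
})
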