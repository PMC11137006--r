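test_that("random directions are unit vectors; the printed scheme is non-uniform", {
  set.seed(31)
  d <- random_direction(5000)
  expect_equal(sqrt(rowSums(d^2)), rep(1, 5000), tolerance = 1e-12)
  # printed construction: z = cos(phi), phi ~ U[0, 2pi], so E|z| = 2/pi
  expect_lt(abs(mean(abs(d[, 3])) - 2 / pi), 4 * 0.31 / sqrt(5000))
  # area-uniform alternative: resultant passes a Rayleigh-type test
  du <- random_direction(5000, uniform = TRUE)
  expect_equal(sqrt(rowSums(du^2)), rep(1, 5000), tolerance = 1e-12)
  S <- 3 * sum(colSums(du)^2) / 5000
  expect_lt(S, qchisq(0.999, df = 3))
})

test_that("direction resampling follows the binomial law", {
  set.seed(17)
  d <- random_direction(1e5)
  out <- resample_direction(d, dt = 0.1, t_per = 10)
  n_hit <- sum(attr(out, "resampled"))
  expect_lt(abs(n_hit - 1000), 4 * sqrt(1e5 * 0.01 * 0.99))
  expect_equal(sqrt(rowSums(out^2)), rep(1, 1e5), tolerance = 1e-12)
  # kept rows are bitwise unchanged
  keep <- !attr(out, "resampled")
  expect_identical(out[keep, ], d[keep, ])
  # infinite persistence time: never resampled
  out2 <- resample_direction(d[1:1000, ], dt = 0.1, t_per = Inf)
  expect_false(any(attr(out2, "resampled")))
})

test_that("migration velocity blends bias and randomness at constant speed", {
  d <- rbind(c(1, 0, 0))
  d_r <- rbind(c(0, 1, 0))
  expect_equal(migration_velocity(d, d_r, b = 1, v_mot = 2),
               rbind(c(2, 0, 0)))
  expect_equal(migration_velocity(d, d_r, b = 0, v_mot = 2),
               rbind(c(0, 2, 0)))
  v <- migration_velocity(d, d_r, b = 0.5, v_mot = 2)
  expect_equal(sqrt(sum(v^2)), 2, tolerance = 1e-12)
  # degenerate blend (d = -d_r at b = 0.5) falls back to the random direction
  vd <- migration_velocity(rbind(c(-1, 0, 0)), rbind(c(1, 0, 0)), b = 0.5,
                           v_mot = 2)
  expect_equal(vd, rbind(c(2, 0, 0)))
  expect_equal(migration_velocity(d, d_r, b = 0.5, v_mot = 2,
                                  attached = TRUE),
               rbind(c(0, 0, 0)))
  # property: speed is v_mot for random unit inputs
  set.seed(5)
  dm <- random_direction(200, uniform = TRUE)
  drm <- random_direction(200)
  vm <- migration_velocity(dm, drm, b = 0.5, v_mot = 2)
  expect_equal(sqrt(rowSums(vm^2)), rep(2, 200), tolerance = 1e-12)
})

test_that("adhesion requires range, recognition, and the stochastic gate", {
  tc <- list(x = 50, y = 50, z = 50)
  far <- tibble::tibble(x = 70, y = 50, z = 50, o = 1.5)   # 20 um > R_LA
  expect_identical(attempt_adhesion(tc, far, dt = 1, r_adh = 10), NA_integer_)
  type4 <- tibble::tibble(x = 55, y = 50, z = 50, o = 0.4)
  expect_identical(attempt_adhesion(tc, type4, dt = 1, r_adh = 10),
                   NA_integer_)
  expect_identical(attempt_adhesion(tc, type4, dt = 1, r_adh = 10,
                                    mode = "multi_antigen"), 1L)
  # nearest eligible target wins; dead cells are skipped
  two <- tibble::tibble(x = c(60, 55, 54), y = 50, z = 50, o = 1,
                        death = c("none", "none", "apoptosis"))
  expect_identical(attempt_adhesion(tc, two, dt = 1, r_adh = 10), 2L)
  # per-step probability r_adh * dt
  set.seed(23)
  near <- tibble::tibble(x = 55, y = 50, z = 50, o = 1)
  hits <- sum(vapply(1:20000, function(i) {
    !is.na(attempt_adhesion(tc, near, dt = 0.1, r_adh = 0.2))
  }, logical(1)))
  expect_lt(abs(hits - 20000 * 0.02), 4 * sqrt(20000 * 0.02 * 0.98))
})

test_that("kill attempts follow the geometric waiting-time law", {
  set.seed(29)
  n <- 10000
  # cohort of attachments to o = 1 targets: mean time to kill = 1/(r_K o)
  waits <- rep(NA_real_, n)
  clock <- rep(0, n)
  active <- seq_len(n)
  while (length(active) > 0) {
    clock[active] <- clock[active] + 0.1
    out <- attempt_kill(o = 1, clock = clock[active], dt = 0.1,
                        t_attach = Inf)
    killed <- out == "kill"
    waits[active[killed]] <- clock[active[killed]]
    active <- active[!killed]
  }
  expect_lt(abs(mean(waits) - 1 / 0.06) / (1 / 0.06), 0.05)
  # sub-threshold target: never killed, detaches exactly at the timeout
  set.seed(30)
  clock <- 0
  status <- "stay"
  while (status == "stay") {
    clock <- clock + 0.1
    status <- attempt_kill(o = 0.4, clock = clock, dt = 0.1, t_attach = 60)
  }
  expect_identical(status, "detach")
  expect_equal(clock, 60, tolerance = 1e-9)
  # multi-antigen mode applies the o = 1 law regardless of expression
  set.seed(31)
  p_hat <- mean(attempt_kill(o = rep(0.1, 2e5), clock = 0, dt = 0.1,
                             mode = "multi_antigen", t_attach = Inf) == "kill")
  expect_lt(abs(p_hat - 0.006), 4 * sqrt(0.006 * 0.994 / 2e5))
  # a dead target yields detach with no kill
  expect_identical(unique(attempt_kill(o = 1, clock = c(0, 30), dt = 0.1,
                                       target_dead = TRUE)), "detach")
})

test_that("lifespans match the zero-truncated normal oracle", {
  set.seed(37)
  l <- draw_lifespan(1e4)
  expect_true(all(l > 0))
  mu_trunc <- truncated_lifespan_mean(10, 5)
  expect_equal(mu_trunc, 10 + 5 * dnorm(-2) / (1 - pnorm(-2)))
  expect_lt(abs(mean(l) - mu_trunc), 4 * 5 / sqrt(1e4))
  # long-term persistence: alive at day 30 regardless of draw
  ll <- draw_lifespan(100, long_term = TRUE)
  expect_true(all(check_exhaustion(30, ll)))
  # age 0 is always alive; exhaustion is permanent once age exceeds lifespan
  expect_true(all(check_exhaustion(0, l)))
  expect_false(any(check_exhaustion(l + 0.01, l)))
})

test_that("dosed T-cells land in free space outside the organoid", {
  set.seed(41)
  cancer <- tibble::tibble(x = rnorm(200, 150, 20), y = rnorm(200, 150, 20),
                           z = rnorm(200, 150, 20))
  pos <- place_dose(100, cancer, domain = 300, R_cell = 8.4)
  com <- colMeans(as.matrix(cancer))
  rb <- sqrt(max(rowSums(sweep(as.matrix(cancer), 2, com)^2)))
  d <- sqrt(rowSums(sweep(pos, 2, com)^2))
  expect_true(all(d > rb + 2 * 8.4))
  expect_true(all(pos >= 0 & pos <= 300))
})
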