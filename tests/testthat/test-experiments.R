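test_that("organoid seeding gives the exact count, radius and spacing", {
  set.seed(51)
  cfg <- experiment_config(domain_size = 1000)
  cells <- seed_organoid(500, cfg)
  expect_identical(nrow(cells), 500L)
  centre <- rep(500, 3)
  r <- sqrt((cells$x - centre[1])^2 + (cells$y - centre[2])^2 +
              (cells$z - centre[3])^2)
  a <- 2 * 8.4 * sqrt(2)
  expect_lt(max(r), (3 * 500 / (4 * pi * 4 / a^3))^(1 / 3) + a)
  # no pathological overlap at seeding
  pos <- as.matrix(cells[, c("x", "y", "z")])
  expect_gte(min(dist(pos)), 1.8 * 8.4)
  # all draws in support, types consistent with o
  expect_true(all(cells$o >= 0 & cells$o <= 2))
  expect_identical(cells$type, classify_type(cells$o))
  # single cell sits at the domain centre
  one <- seed_organoid(1, cfg)
  expect_lt(max(abs(c(one$x, one$y, one$z) - centre)), a)
  # a sphere that cannot fit is rejected
  expect_error(seed_organoid(4000, desk_config(n_cells = 4000)), "domain")
})

test_that("growth-rate estimation recovers exact exponentials and flags zeros", {
  tt <- seq(0, 10 * 1440, by = 1440)
  k <- 0.31
  m <- tibble::tibble(time = tt, live_cancer = 100 * exp(k * tt / 1440))
  expect_equal(growth_rate(m, window = 5), k, tolerance = 1e-10)
  expect_equal(growth_rate(m, window = 10), k, tolerance = 1e-10)
  const <- tibble::tibble(time = tt, live_cancer = rep(42, length(tt)))
  expect_equal(growth_rate(const), 0, tolerance = 1e-12)
  zero <- tibble::tibble(time = tt, live_cancer = c(rep(10, 10), 0))
  expect_warning(gr <- growth_rate(zero), "undefined")
  expect_true(is.na(gr))
  expect_error(growth_rate(m[1:2, ], window = 30), "at least 3")
})

test_that("dead-per-CAR-T arithmetic and the pigeonhole implication hold", {
  ledger <- tibble::tibble(kills = c(rep(2, 100), rep(0, 0)))
  ledger$kills[1:50] <- 3
  ledger$kills[51:100] <- 2
  out <- dead_per_cart(ledger)
  expect_equal(out$ratio, mean(ledger$kills))
  expect_identical(out$free_tcells, 0L)
  allfree <- tibble::tibble(kills = rep(0, 25))
  out2 <- dead_per_cart(allfree)
  expect_equal(out2$ratio, 0)
  expect_identical(out2$free_tcells, 25L)
  expect_error(dead_per_cart(tibble::tibble(kills = integer(0))),
               "no CAR T-cells")
  # ratio < 1 implies at least one T-cell with zero kills (integer pigeonhole)
  set.seed(61)
  for (i in 1:50) {
    kills <- rpois(20, runif(1, 0, 2))
    r <- dead_per_cart(tibble::tibble(kills = kills))
    if (r$ratio < 1) expect_gt(r$free_tcells, 0)
  }
})

test_that("radial distribution conserves counts and is flat for uniform balls", {
  # all cells of one type in one shell
  pop <- tibble::tibble(x = 100 + c(30, -30, 30), y = 100 + c(0, 0, 3),
                        z = 100, type = 2L, death = "none")
  g <- radial_distribution(pop, shell_width = 42)
  expect_equal(sum(g$count[g$class == "type2"]), 3)
  expect_true(all(g$count[g$class != "type2"] == 0))
  expect_equal(g$density, g$count / (4 / 3 * pi * (g$r_outer^3 - g$r_inner^3)))
  # conservation: sum(density * shell volume) returns each class total
  set.seed(71)
  n <- 10000
  u <- matrix(rnorm(3 * n), n, 3)
  u <- u / sqrt(rowSums(u^2)) * 100 * runif(n)^(1 / 3)   # uniform in a ball
  pop2 <- tibble::tibble(x = u[, 1], y = u[, 2], z = u[, 3],
                         type = sample(1:4, n, TRUE), death = "none")
  g2 <- radial_distribution(pop2, shell_width = 20)
  totals <- tapply(g2$count, g2$class, sum)
  expect_equal(as.numeric(totals[paste0("type", 1:4)]),
               as.numeric(table(pop2$type)))
  # interior shells of a uniform ball have a flat density profile
  dens <- g2 |>
    dplyr::group_by(shell) |>
    dplyr::summarise(density = sum(density), r_outer = max(r_outer))
  interior <- dens$density[dens$r_outer <= 80 & dens$r_outer > 20]
  expect_true(all(abs(interior - mean(interior)) / mean(interior) < 0.1))
})

test_that("identical configurations and seeds reproduce metrics bitwise", {
  cfg <- smoke_config(n_cells = 80, days = 0.5, seed = 99,
                      dose_days = 0.1, dose_ratios = 1)
  s1 <- simulate_organoid(cfg)
  s2 <- simulate_organoid(cfg)
  expect_identical(s1$metrics, s2$metrics)
  expect_identical(s1$kill_ledger, s2$kill_ledger)
  # manifest round trip reproduces the run
  s3 <- simulate_from_manifest(run_manifest(s1))
  expect_identical(s1$metrics, s3$metrics)
})

test_that("a treated smoke run satisfies the bookkeeping invariants", {
  cfg <- smoke_config(n_cells = 120, days = 1.5, seed = 103,
                      dose_days = 0.25, dose_ratios = 1)
  sim <- simulate_organoid(cfg)
  m <- sim$metrics
  expect_true(all(diff(m$cum_dead) >= 0))
  expect_true(all(diff(m$cum_kills) >= 0))
  fr <- m$frac_type1 + m$frac_type2 + m$frac_type3 + m$frac_type4
  expect_equal(fr[m$live_cancer > 0], rep(1, sum(m$live_cancer > 0)),
               tolerance = 1e-12)
  # every kill is attributed to exactly one T-cell
  expect_identical(sum(sim$kill_ledger$kills), as.integer(tail(m$cum_kills, 1)))
  expect_equal(sum(sim$kills_by_type), tail(m$cum_kills, 1))
  # kills cannot exceed cancer deaths, deaths cannot exceed ever-born cells
  expect_lte(tail(m$cum_kills, 1), tail(m$cum_dead, 1))
  expect_lte(tail(m$cum_dead, 1), 120 + sim$counters$cum_born)
  # dose size respects the ratio rule
  expect_identical(nrow(sim$kill_ledger), as.integer(sim$counters$dose_base_n))
  # selection: with kills present, survivor mean oncoprotein cannot exceed
  # the pre-treatment mean
  if (tail(m$cum_kills, 1) > 0) {
    expect_lte(tail(m$mean_oncoprotein, 1), m$mean_oncoprotein[1] + 1e-9)
  }
  # tidy/glance/autoplot surfaces
  td <- tidy(sim)
  expect_true(all(c("time", "day", "metric", "value") %in% names(td)))
  gl <- glance(sim)
  expect_identical(nrow(gl), 1L)
  expect_identical(gl$tcells_administered, nrow(sim$kill_ledger))
  expect_s3_class(autoplot(sim), "ggplot")
  expect_s3_class(plot_type_fractions(sim), "ggplot")
  expect_s3_class(plot_radial_distribution(radial_distribution(sim$final_cancer)),
                  "ggplot")
})

test_that("attached targets are frozen and the immune ledger tracks doses", {
  cfg <- smoke_config(n_cells = 60, days = 1, seed = 107,
                      dose_days = c(0.1, 0.6), dose_ratios = c(0.5, 0.5))
  sim <- simulate_organoid(cfg)
  expect_identical(sort(unique(sim$kill_ledger$dose)), c(1L, 2L))
  # equal-ratio second dose delivers the same absolute count
  n1 <- sum(sim$kill_ledger$dose == 1)
  n2 <- sum(sim$kill_ledger$dose == 2)
  expect_identical(n1, n2)
  expect_identical(nrow(sim$kill_ledger), n1 + n2)
})
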