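test_that("the oscillator conserves symmetry and matches its analytic period", {
  at_rest <- build_oscillator(displacement = 0)
  p0 <- positions(at_rest)
  sim_run(at_rest, 200)
  expect_equal(positions(at_rest), p0)          # static at the rest length

  u <- build_oscillator(k = 2, m = 1.5, displacement = 0.3, dt = 0.002)
  com0 <- colMeans(positions(u))
  # measure the period from separation zero crossings
  prev <- NULL; crossings <- numeric(0)
  for (s in 1:3000) {
    sim_step(u)
    x <- diff(positions(u)[, 1]) - 1
    if (!is.null(prev) && prev < 0 && x >= 0) {
      crossings <- c(crossings, (s - 1 + prev / (prev - x)) * u$dt)
    }
    prev <- x
  }
  expect_lt(max(abs(colMeans(positions(u)) - com0)), 1e-12)  # COM stationary
  period <- unname(diff(crossings)[1])
  expect_equal(period, oscillator_period(k = 2, m = 1.5), tolerance = 0.01)
})

test_that("the pendulum pivot stays fixed and stiff bonds stay near rest length", {
  u <- build_pendulum(g = 1, k = 100, r0 = 1)
  excursion <- 0
  for (b in 1:40) {
    sim_step(u, 25)
    p <- positions(u)
    expect_equal(p[1, ], c(5, 5, 8))            # frozen pivot never moves
    l1 <- sqrt(sum((p[2, ] - p[1, ])^2))
    l2 <- sqrt(sum((p[3, ] - p[2, ])^2))
    excursion <- max(excursion, abs(l1 - 1), abs(l2 - 1))
  }
  expect_lt(excursion, 0.05)                    # <= 5% bond-length excursion
  still <- build_pendulum(g = 0)
  p0 <- positions(still)
  sim_run(still, 100)
  expect_equal(positions(still), p0)            # no gravity, no motion
})

test_that("spheroid assembly relaxes to the potential minimum", {
  two <- assemble_spheroid(2, seed = 4)
  sep <- sqrt(sum((two[1, ] - two[2, ])^2))
  expect_equal(sep, 1, tolerance = 0.05)        # Morse minimum at r0 = 1
  small <- assemble_spheroid(40, seed = 4)
  expect_lt(max(abs(colMeans(small))), 0.2)     # centred on the origin
  expect_error(assemble_spheroid(1), "n_cells >= 2")
})

test_that("neck_diameter equals the dense pairwise oracle", {
  pos <- rbind(c(0, 0, 0), c(0.2, 3, 1), c(-0.1, 1, 5))
  expect_equal(neck_diameter(pos, "y", 0, 0.5), 3)
  expect_equal(neck_diameter(pos[1, , drop = FALSE], "y", 0, 0.5), 0)
  expect_equal(neck_diameter(pos, "y", 40, 0.5), 0)    # empty slab
  set.seed(10)
  for (rep in 1:20) {
    p <- cbind(runif(50, -2, 2), runif(50, -5, 5), runif(50, -5, 5))
    got <- neck_diameter(p, "z", 0, 1)
    slab <- abs(p[, 1]) <= 1
    want <- 0
    idx <- which(slab)
    for (a in idx) for (b in idx) want <- max(want, abs(p[a, 3] - p[b, 3]))
    expect_equal(got, want)
  }
})

test_that("crypt cycle bookkeeping follows the phase rules", {
  geom <- list(height = 10, prolif_frac = 2 / 3)
  # S phase with time remaining: clock decrements, no actions
  a <- crypt_cell_actions(2L, 0.8, 3, 0.1, geom)
  expect_equal(a$remaining, 0.7)
  expect_false(a$advance || a$divide || a$remove)
  # M phase expiry emits a division
  a <- crypt_cell_actions(4L, 0.05, 3, 0.1, geom)
  expect_true(a$divide); expect_false(a$advance)
  # outside the proliferative zone the clock pauses
  a <- crypt_cell_actions(4L, 0.05, 8, 0.1, geom)
  expect_equal(a$remaining, 0.05)
  expect_false(a$divide)
  # contact inhibition pauses the clock too
  a <- crypt_cell_actions(4L, 0.05, 3, 0.1, geom, crowded = TRUE)
  expect_false(a$divide)
  # reaching the base emits removal
  a <- crypt_cell_actions(1L, 5, 10.2, 0.1, geom)
  expect_true(a$remove)
})

test_that("daughters inherit the parent clone id and clone counting is exact", {
  u <- build_crypt(20, seed = 3, params = list(width = 6, height = 6))
  expect_equal(count_clones(u), 20)
  clones0 <- sort(unique(u$model$crypt$clone[particle_ids(u) + 1L]))
  sim_run(u, 600)   # long enough for divisions and removals
  expect_gt(u$id_next, 20)                     # divisions occurred
  live <- particle_ids(u)
  clones <- u$model$crypt$clone[live + 1L]
  expect_true(all(clones %in% clones0))        # ids copied, never minted
  expect_equal(count_clones(u), length(unique(clones)))
})

test_that("an unconstrained proliferative population doubles per cycle", {
  # all-proliferative, no-removal variant: pure branching process
  p <- list(width = 30, height = 30, prolif_frac = 1.1, ci_neighbors = 1000,
            g1_mean = 2, g1_sd = 0.5)
  u <- build_crypt(50, seed = 6, params = p)
  t_total <- 10                                # two mean cycles of 5
  sim_run(u, round(t_total / u$dt))
  n <- particle_count(u)
  expected <- 50 * 2^(t_total / 5)
  expect_gt(n, expected * 0.7)
  expect_lt(n, expected * 1.45)
})

test_that("the lateral-inhibition ODEs have the stated structure", {
  p <- collier_params()
  r <- collier_rhs(0, 0, 0, p)
  expect_equal(r$dn, 0)                        # F(0) = 0
  expect_equal(r$dd, p$v * 1)                  # G(0) = 1
  fp <- collier_fixed_point(p)
  rr <- collier_rhs(fp$n, fp$d, fp$d, p)
  expect_lt(abs(rr$dn), 1e-10)
  expect_lt(abs(rr$dd), 1e-10)
  expect_error(collier_rhs(-0.1, 0, 0, p), "nonnegative")
})

test_that("a small sheet patterns with anti-correlated neighbor Delta", {
  u <- build_delta_notch(8, 8, seed = 2)
  sim_run(u, 900)
  expect_lt(neighbor_delta_correlation(u), -0.3)
  d <- get_species(u, u$model$dn$ids, "delta")
  expect_gt(max(d), 0.8)                       # high-Delta cells emerge
  expect_lt(min(d), 0.1)                       # inhibited neighbors
})

test_that("membrane pump conserves cargo and moves it upward only", {
  u <- build_membrane_pump(n_fluid = 40, seed = 4)
  tot0 <- compartment_totals(u)$total
  ups <- numeric(20)
  for (b in 1:20) {
    sim_step(u, 10)
    ct <- compartment_totals(u)
    expect_lt(abs(ct$total - tot0), 1e-11)
    ups[b] <- ct$upper
  }
  expect_true(all(diff(ups) >= -1e-12))        # upper totals never decrease
  expect_gt(ups[20], 0)                        # the pump moved cargo
  frozen_rate <- build_membrane_pump(n_fluid = 20, pump_k = 0, seed = 4)
  c0 <- compartment_totals(frozen_rate)
  sim_run(frozen_rate, 100)
  c1 <- compartment_totals(frozen_rate)
  expect_equal(c1$lower, c0$lower, tolerance = 1e-12)
  expect_equal(c1$upper, c0$upper, tolerance = 1e-12)
})

test_that("the signal grid stays uniform without a source and fronts advance monotonically", {
  u <- build_signal_grid(nx = 8, ny = 8, D = 0.1, dt = 0.1, seed = 3)
  ids <- u$model$grid$ids
  set_species(u, ids, "signal", 0.4)
  sim_run(u, 50)
  expect_equal(unname(get_species(u, ids, "signal")), rep(0.4, 64))
  # with an edge source, farther rows rise later but monotonically in time
  us <- build_signal_grid(nx = 8, ny = 8, D = 0.2, dt = 0.1, seed = 3,
                          source_edge = TRUE)
  rows <- rep(1:8, each = 8)
  lvl <- matrix(0, 30, 8)
  for (b in 1:30) {
    sim_step(us, 5)
    s <- get_species(us, us$model$grid$ids, "signal")
    lvl[b, ] <- tapply(s, rows, mean)
  }
  for (rw in 2:8) expect_true(all(diff(lvl[, rw]) >= -1e-12))
  expect_true(all(diff(lvl[30, ]) <= 1e-12))   # closer rows are at least as high
  expect_gt(local_signal(us, c(4, 1, 2), 1.5), local_signal(us, c(4, 8, 2), 1.5))
})
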