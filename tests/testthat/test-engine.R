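test_that("the cell grid partitions the domain by cutoff", {
  u <- universe(dims = c(10, 10, 10), cutoff = 5, boundary = "periodic")
  g <- build_cell_grid(u)
  expect_equal(g$counts, c(2L, 2L, 2L))
  u2 <- universe(dims = c(10, 10, 10), cutoff = 3, boundary = "reflective")
  g2 <- build_cell_grid(u2)
  expect_equal(g2$counts, c(3L, 3L, 3L))
  expect_equal(g2$cell_size, rep(10 / 3, 3))
  # no duplicate unordered neighbor cell pairs even for tiny grids
  for (co in c(5, 3)) {
    uu <- universe(dims = c(10, 10, 10), cutoff = co, boundary = "periodic")
    gg <- build_cell_grid(uu)
    key <- pmin(gg$pair_a, gg$pair_b) * gg$n_cells + pmax(gg$pair_a, gg$pair_b)
    expect_false(any(duplicated(key)))
  }
})

test_that("particles are re-indexed when they cross cell boundaries", {
  u <- universe(dims = c(10, 10, 10), cutoff = 2.5, dt = 0.1,
                boundary = "periodic")
  register_type(u, particle_type("A", dynamics = "newtonian"))
  id <- create_particle(u, "A", c(2.4, 1, 1), velocity = c(1, 0, 0))
  g <- build_cell_grid(u)
  before <- tissuesim:::.cell_of(u, 1L, g)
  sim_step(u, 2)   # moves to x = 2.6, into the next cell
  after <- tissuesim:::.cell_of(u, 1L, g)
  expect_false(identical(before, after))
})

test_that("sort_cell orders by projection with stable id tie-breaks", {
  u <- universe(dims = c(10, 10, 10), cutoff = 2)
  register_type(u, particle_type("A"))
  create_particle(u, "A", rbind(c(3, 1, 1), c(1, 1, 1), c(2, 1, 1),
                                c(1, 5, 1)))
  ord <- sort_cell(u, 1:4, c(1, 0, 0))
  expect_equal(u$pos[ord, 1], c(1, 1, 2, 3))
  expect_equal(ord[1:2], c(2L, 4L))   # equal projections: ascending id order
  expect_identical(sort_cell(u, integer(0), c(1, 0, 0)), integer(0))
})

test_that("cell-list pair enumeration equals the dense scan", {
  for (mode in c("periodic", "reflective")) {
    for (cutoff in c(1, 2.5)) {
      u <- random_universe(80, dims = c(8, 9, 10), cutoff = cutoff,
                           boundary = mode, seed = cutoff * 10 + 1)
      pairs <- tissuesim:::enumerate_pairs(u)
      got <- sort(paste(pmin(pairs$ii, pairs$jj), pmax(pairs$ii, pairs$jj)))
      pos <- positions(u)
      want <- character(0)
      for (i in 1:79) for (j in (i + 1):80) {
        d <- mi_disp(pos[i, ], pos[j, ], u$dims, u$boundary)
        if (sum(d^2) < cutoff^2) want <- c(want, paste(i, j))
      }
      expect_identical(got, sort(want))
    }
  }
})

test_that("forces from the cell list equal the dense oracle", {
  u <- random_universe(200, dims = c(10, 10, 10), cutoff = 2,
                       boundary = "periodic", seed = 20)
  pot <- potential_harmonic(1, 1, r_max = 2)
  bind_potential(u, "A", "A", pot)
  pe <- compute_forces(u)
  ref <- brute_forces(positions(u), u$dims, u$boundary, u$cutoff,
                      function(r) (r - 1)^2, function(r) 2 * (r - 1))
  expect_lt(max(abs(u$force[1:200, ] - ref$force)), 1e-10)
  expect_lt(abs(pe - ref$energy), 1e-10)
  # no bindings -> zero accumulators
  u0 <- random_universe(50, dims = c(10, 10, 10), cutoff = 2,
                        boundary = "periodic", seed = 21)
  compute_forces(u0)
  expect_equal(max(abs(u0$force)), 0)
})

test_that("bound and unbound modes scope interactions by top-level cluster", {
  u <- universe(dims = c(20, 20, 20), cutoff = 3, boundary = "reflective")
  register_type(u, particle_type("A", dynamics = "newtonian"))
  set.seed(8)
  c1 <- create_particle(u, "A", matrix(runif(30, 8, 10), 10, 3))
  c2 <- create_particle(u, "A", matrix(runif(30, 10, 12), 10, 3))
  new_cluster(u, particle_ids = c1)
  new_cluster(u, particle_ids = c2)
  bind_potential(u, "A", "A", potential_harmonic(1, 1, r_max = 3),
                 mode = "bound")
  compute_forces(u)
  f_bound <- u$force[1:20, ]
  # dense oracle restricted to same-cluster pairs
  pos <- positions(u)
  ref <- matrix(0, 20, 3)
  for (i in 1:19) for (j in (i + 1):20) {
    same <- (i <= 10) == (j <= 10)
    if (!same) next
    d <- pos[j, ] - pos[i, ]
    r <- sqrt(sum(d^2))
    if (r < 3) {
      fi <- (2 * (r - 1) / r) * d
      ref[i, ] <- ref[i, ] + fi
      ref[j, ] <- ref[j, ] - fi
    }
  }
  expect_lt(max(abs(f_bound - ref)), 1e-10)
  # unbound mode: complementary pair set
  u$bindings <- list()
  bind_potential(u, "A", "A", potential_harmonic(1, 1, r_max = 3),
                 mode = "unbound")
  u$force[] <- 0
  compute_forces(u)
  ref2 <- matrix(0, 20, 3)
  for (i in 1:19) for (j in (i + 1):20) {
    same <- (i <= 10) == (j <= 10)
    if (same) next
    d <- pos[j, ] - pos[i, ]
    r <- sqrt(sum(d^2))
    if (r < 3) {
      fi <- (2 * (r - 1) / r) * d
      ref2[i, ] <- ref2[i, ] + fi
      ref2[j, ] <- ref2[j, ] - fi
    }
  }
  expect_lt(max(abs(u$force[1:20, ] - ref2)), 1e-10)
})

test_that("stepping integrates the stated first-order updates", {
  # no forces: positions unchanged, time advances
  u <- random_universe(10, dims = c(10, 10, 10), cutoff = 1,
                       boundary = "periodic", seed = 30)
  p0 <- positions(u)
  sim_step(u)
  expect_equal(positions(u), p0)
  expect_equal(u$time, u$dt)
  expect_identical(u$step_count, 1L)

  # overdamped constant force: displacement n dt f / m, exactly
  u2 <- universe(dims = c(50, 20, 20), cutoff = 1, dt = 0.05,
                 boundary = "reflective")
  register_type(u2, particle_type("O", mass = 2, dynamics = "overdamped"))
  id <- create_particle(u2, "O", c(5, 10, 10))
  bind_force(u2, "O", force_constant(c(3, 0, 0)))
  sim_step(u2, 40)
  expect_equal(get_particle(u2, id)$position[1], 5 + 40 * 0.05 * 3 / 2)

  # frozen particles accumulate force but never move
  u3 <- universe(dims = c(10, 10, 10), cutoff = 1, dt = 0.01,
                 boundary = "reflective")
  register_type(u3, particle_type("F", dynamics = "newtonian", frozen = TRUE))
  fid <- create_particle(u3, "F", c(5, 5, 5))
  bind_force(u3, "F", force_constant(c(1, 0, 0)))
  sim_step(u3, 10)
  expect_equal(get_particle(u3, fid)$position, c(5, 5, 5))
  expect_equal(get_particle(u3, fid)$force[1], 1)
})

test_that("momentum is conserved under pure pair forces", {
  u <- random_universe(40, dims = c(10, 10, 10), cutoff = 2,
                       boundary = "periodic", seed = 31, dt = 0.002,
                       vel_sd = 0.2)
  bind_potential(u, "A", "A", potential_morse(0.5, 2, 1, r_min = 0.3, r_max = 2))
  p0 <- colSums(velocities(u))
  sim_run(u, 1000)
  expect_lt(max(abs(colSums(velocities(u)) - p0)), 1e-9)
})

test_that("identical seed and configuration give bitwise-identical trajectories", {
  mk <- function() {
    u <- universe(dims = c(8, 8, 8), cutoff = 1, dt = 0.01,
                  boundary = "periodic", seed = 99)
    register_type(u, particle_type("F", mass = 1, dynamics = "newtonian"))
    set.seed(12)
    create_particle(u, "F", matrix(runif(90, 0, 8), 30, 3))
    bind_potential(u, "F", "F", potential_dpd(10, 4.5, 3, 1))
    u
  }
  a <- mk(); sim_run(a, 200)
  b <- mk(); sim_run(b, 200)
  expect_identical(positions(a), positions(b))
  expect_identical(velocities(a), velocities(b))
})

test_that("total energy decomposes into kinetic and pair-counted potential", {
  u <- random_universe(60, dims = c(10, 10, 10), cutoff = 2,
                       boundary = "periodic", seed = 33, vel_sd = 0.3)
  bind_potential(u, "A", "A", potential_harmonic(1, 1, r_max = 2))
  compute_forces(u)
  en <- total_energy(u)
  v <- velocities(u)
  expect_equal(en$kinetic, sum(0.5 * rowSums(v^2)))
  ref <- brute_forces(positions(u), u$dims, u$boundary, u$cutoff,
                      function(r) (r - 1)^2, function(r) 2 * (r - 1))
  expect_lt(abs(en$potential - ref$energy), 1e-10)
  # rest, no bindings -> (0, 0)
  u0 <- random_universe(5, dims = c(10, 10, 10), cutoff = 1,
                        boundary = "periodic", seed = 34)
  compute_forces(u0)
  e0 <- total_energy(u0)
  expect_equal(e0$kinetic, 0)
  expect_equal(e0$potential, 0)
})

test_that("a non-finite trajectory aborts with a diagnostic naming the particle", {
  u <- universe(dims = c(10, 10, 10), cutoff = 1, dt = 0.01,
                boundary = "reflective")
  register_type(u, particle_type("A", dynamics = "newtonian"))
  create_particle(u, "A", c(5, 5, 5))
  bind_force(u, "A", force_custom(function(uu, ids) matrix(Inf, length(ids), 3)))
  expect_error(sim_step(u), "particle id 0.*Update")
})
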