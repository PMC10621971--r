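u_open <- function() universe(dims = c(20, 20, 20), cutoff = 2,
                              boundary = "reflective")

test_that("bond energy and forces follow the distance potential", {
  u <- u_open()
  pot <- potential_harmonic(2, 1)
  r <- bond_energy_forces(pot, c(5, 5, 5), c(6, 5, 5), u)
  expect_equal(r$energy, 0)
  expect_equal(r$f_i, c(0, 0, 0))
  set.seed(3)
  for (rep in 1:20) {
    X <- matrix(runif(6, 4, 9), 2, 3)
    res <- bond_energy_forces(pot, X[1, ], X[2, ], u)
    expect_identical(res$f_i + res$f_j, c(0, 0, 0))    # exact third law
    g <- num_grad(function(Y) bond_energy_forces(pot, Y[1, ], Y[2, ], u)$energy, X)
    expect_lt(max(abs(rbind(res$f_i, res$f_j) + g)), 1e-6)
  }
  expect_error(bond_energy_forces(pot, c(1, 1, 1), c(1, 1, 1), u), "coincident")
})

test_that("angle terms reproduce geometry and the analytic gradient", {
  u <- u_open()
  pot <- potential_harmonic(1.5, pi / 3)
  r <- angle_energy_forces(pot, c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), u)
  expect_equal(r$theta, pi / 2)
  set.seed(4)
  for (rep in 1:20) {
    X <- matrix(runif(9, 4, 9), 3, 3)
    res <- angle_energy_forces(pot, X[1, ], X[2, ], X[3, ], u)
    an <- rbind(res$f_i, res$f_j, res$f_k)
    expect_lt(max(abs(colSums(an))), 1e-10)
    # net torque about the pivot vanishes
    tq <- tissuesim:::.cross(X[1, ] - X[2, ], res$f_i) +
          tissuesim:::.cross(X[3, ] - X[2, ], res$f_k)
    expect_lt(max(abs(tq)), 1e-10)
    g <- num_grad(function(Y) angle_energy_forces(pot, Y[1, ], Y[2, ], Y[3, ], u)$energy, X)
    expect_lt(max(abs(an + g)), 1e-5)
  }
  # collinear guard: bounded (zero) forces, finite energy
  res <- angle_energy_forces(pot, c(1, 0, 0), c(0, 0, 0), c(2, 0, 0), u)
  expect_equal(res$f_i, c(0, 0, 0))
  expect_error(angle_energy_forces(pot, c(0, 0, 0), c(0, 0, 0), c(1, 0, 0), u),
               "zero length")
})

test_that("dihedral terms follow the sign convention and analytic gradient", {
  u <- u_open()
  pot <- potential_harmonic(0.8, 0.3, r_min = -pi)
  # planar cis configuration -> phi = 0
  r <- dihedral_energy_forces(pot, c(1, 1, 0), c(1, 0, 0), c(2, 0, 0),
                              c(2, 1, 0), u)
  expect_equal(r$phi, 0)
  r <- dihedral_energy_forces(pot, c(1, 1, 0), c(1, 0, 0), c(2, 0, 0),
                              c(2, -1, 0), u)
  expect_equal(abs(r$phi), pi)
  set.seed(5)
  for (rep in 1:20) {
    X <- matrix(runif(12, 4, 9), 4, 3)
    res <- dihedral_energy_forces(pot, X[1, ], X[2, ], X[3, ], X[4, ], u)
    an <- rbind(res$f_i, res$f_j, res$f_k, res$f_l)
    expect_lt(max(abs(colSums(an))), 1e-10)
    g <- num_grad(function(Y) dihedral_energy_forces(pot, Y[1, ], Y[2, ],
                                                     Y[3, ], Y[4, ], u)$energy, X)
    expect_lt(max(abs(an + g)), 1e-5)
    # translation invariance
    sh <- sweep(X, 2, c(0.3, -0.2, 0.5), "+")
    res2 <- dihedral_energy_forces(pot, sh[1, ], sh[2, ], sh[3, ], sh[4, ], u)
    expect_equal(res2$energy, res$energy)
    expect_equal(res2$f_i, res$f_i)
  }
  expect_error(dihedral_energy_forces(pot, c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
                                      c(3, 1, 0), u), "degenerate")
})

test_that("bonds act at any length, ignoring the global cutoff", {
  u <- universe(dims = c(30, 30, 30), cutoff = 2, boundary = "reflective")
  register_type(u, particle_type("A", dynamics = "newtonian"))
  ids <- create_particle(u, "A", rbind(c(5, 15, 15), c(25, 15, 15)))
  add_bond(u, ids[1], ids[2], potential_harmonic(1, 1))
  compute_forces(u)
  f <- u$force[1:2, ]
  expect_gt(abs(f[1, 1]), 1)     # stretched to l = 20 >> cutoff, still pulls
  expect_equal(f[1, ], -f[2, ])
})

test_that("bonds use minimum-image separations under periodic boundaries", {
  u <- universe(dims = c(10, 10, 10), cutoff = 2, boundary = "periodic")
  register_type(u, particle_type("A", dynamics = "newtonian"))
  ids <- create_particle(u, "A", rbind(c(0.5, 5, 5), c(9.5, 5, 5)))
  r <- bond_energy_forces(potential_harmonic(1, 1), positions(u)[1, ],
                          positions(u)[2, ], u)
  expect_equal(r$r, 1)           # across the wrap, not 9
  expect_equal(r$energy, 0)
})

test_that("dissociation destroys items exactly when energy exceeds the threshold", {
  u <- u_open()
  register_type(u, particle_type("A", dynamics = "newtonian"))
  ids <- create_particle(u, "A", rbind(c(5, 5, 5), c(6.9487, 5, 5)))
  # harmonic k=1 r0=1: U(1.9487) = 0.9
  add_bond(u, ids[1], ids[2], potential_harmonic(1, 1),
           dissociation_energy = 1.0)
  compute_forces(u)
  expect_equal(u$bonds$energy[1], 0.9, tolerance = 1e-3)
  cull_dissociated(u)
  expect_equal(bond_count(u), 1)                    # 0.9 < 1.0: retained
  set_particle(u, ids[2], position = c(7.1, 5, 5))  # U = 1.1^2 = 1.21
  compute_forces(u)
  culled <- cull_dissociated(u)
  expect_equal(bond_count(u), 0)                    # energy exceeded: destroyed
  # absent threshold: never destroyed
  ids2 <- create_particle(u, "A", rbind(c(2, 2, 2), c(8, 2, 2)))
  add_bond(u, ids2[1], ids2[2], potential_harmonic(5, 1))
  compute_forces(u)
  cull_dissociated(u)
  expect_equal(bond_count(u), 1)
})

test_that("all bonded force maps sum to zero on a toy molecule each step", {
  u <- toy_molecule(seed = 9)
  for (s in 1:50) {
    sim_step(u)
    live <- which(u$alive[seq_len(u$n_slots)])
    expect_lt(max(abs(colSums(u$force[live, , drop = FALSE]))), 1e-10)
    expect_true(all(is.finite(positions(u))))
  }
})
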