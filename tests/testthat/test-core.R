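test_that("type registration enforces the uniqueness contract", {
  u <- universe()
  register_type(u, particle_type("A", mass = 1, dynamics = "newtonian"))
  register_type(u, particle_type("B", mass = 2))
  expect_identical(u$type_names, c("A", "B"))
  expect_equal(get_type(u, "A")$mass, 1)
  expect_error(register_type(u, particle_type("A", mass = 3)),
               "already registered")
  expect_error(particle_type("C", mass = -1), "positive")
  expect_error(particle_type("C", species = c("x", "x")), "duplicates")
})

test_that("particles inherit type attributes and get monotone ids", {
  u <- universe(dims = c(10, 10, 10))
  register_type(u, particle_type("A", mass = 2.5, radius = 0.7,
                                 dynamics = "newtonian"))
  id <- create_particle(u, "A", c(0, 0, 0))
  expect_identical(id, 0L)
  p <- get_particle(u, 0)
  expect_equal(p$velocity, c(0, 0, 0))
  expect_equal(p$mass, 2.5)
  expect_equal(p$radius, 0.7)
  # bulk creation: counting oracle
  more <- create_particle(u, "A", matrix(runif(300, 0, 10), 100, 3))
  expect_identical(more, 1:100)
  expect_equal(particle_count(u), 101)
  expect_error(create_particle(u, "nope", c(0, 0, 0)), "unknown particle type")
  expect_error(create_particle(u, "A", c(NaN, 0, 0)), "finite")
})

test_that("positions wrap at creation under periodic boundaries", {
  u <- universe(dims = c(10, 10, 10), boundary = "periodic")
  register_type(u, particle_type("A"))
  id <- create_particle(u, "A", c(11, 0, 0))
  expect_equal(get_particle(u, id)$position[1], 1)
})

test_that("destroying particles keeps registries consistent and never reuses ids", {
  u <- universe(dims = c(10, 10, 10))
  register_type(u, particle_type("A"))
  ids <- create_particle(u, "A", matrix(runif(30, 2, 8), 10, 3))
  add_bond(u, ids[1], ids[2], potential_harmonic(1, 1))
  add_bond(u, ids[2], ids[3], potential_harmonic(1, 1))
  expect_equal(bond_count(u), 2)
  destroy_particle(u, ids[2])
  expect_equal(bond_count(u), 0)   # both bonds referenced the destroyed particle
  expect_equal(particle_count(u), 9)
  destroy_particle(u, ids[c(4, 5)])
  # id-allocation oracle: create 10, destroy 3, create 1 -> next id is 10
  new_id <- create_particle(u, "A", c(5, 5, 5))
  expect_identical(new_id, 10L)
  expect_error(destroy_particle(u, ids[2]), "not alive")
  expect_error(get_particle(u, 999), "unknown particle id")
})

test_that("live ids stay unique through random create/destroy sequences", {
  u <- universe(dims = c(10, 10, 10))
  register_type(u, particle_type("A"))
  set.seed(42)
  for (op in 1:300) {
    if (runif(1) < 0.6 || particle_count(u) == 0) {
      create_particle(u, "A", runif(3, 0, 10))
    } else {
      ids <- particle_ids(u)
      destroy_particle(u, sample(ids, 1))
    }
    live <- particle_ids(u)
    expect_false(anyDuplicated(live) > 0)
  }
  expect_gt(u$id_next, length(particle_ids(u)))
})

test_that("neighbor_query equals the dense minimum-image scan in both boundary modes", {
  two <- universe(dims = c(10, 10, 10))
  register_type(two, particle_type("A"))
  a <- create_particle(two, "A", c(2, 5, 5))
  b <- create_particle(two, "A", c(4, 5, 5))
  expect_identical(neighbor_query(two, a, 1.0), integer(0))
  expect_identical(neighbor_query(two, a, 3.0), b)

  for (mode in c("periodic", "reflective")) {
    u <- universe(dims = c(8, 8, 8), cutoff = 2, boundary = mode, seed = 3)
    register_type(u, particle_type("A"))
    set.seed(7)
    pos <- matrix(runif(150, 0, 8), 50, 3)
    ids <- create_particle(u, "A", pos)
    for (q in c(1, 5, 20)) {
      got <- neighbor_query(u, ids[q], 1.0)
      want <- ids[brute_neighbors(pos, q, u$dims, u$boundary, 1.0)]
      expect_setequal(got, want)
    }
  }
  lone <- universe(dims = c(8, 8, 8))
  register_type(lone, particle_type("A"))
  lid <- create_particle(lone, "A", c(4, 4, 4))
  expect_identical(neighbor_query(lone, lid, 2), integer(0))
})

test_that("cluster membership is acyclic and scopes top-level resolution", {
  u <- universe(dims = c(10, 10, 10))
  register_type(u, particle_type("A"))
  ids <- create_particle(u, "A", matrix(runif(18, 2, 8), 6, 3))
  inner <- new_cluster(u, particle_ids = ids[1:2])
  outer <- new_cluster(u, particle_ids = ids[3:4], cluster_ids = inner)
  expect_identical(top_cluster(u, ids[1]), outer)   # nested resolves to top
  expect_identical(top_cluster(u, ids[3]), outer)
  expect_true(is.na(top_cluster(u, ids[5])))
  expect_error(cluster_add(u, inner, cluster_ids = outer), "acyclic")
  expect_error(cluster_add(u, inner, particle_ids = ids[1]),
               "already belongs")
  destroy_particle(u, ids[1])
  expect_false(ids[1] %in% u$clusters[[as.character(inner)]]$members)
})

test_that("boundary application wraps, reflects and is idempotent", {
  u <- universe(dims = c(10, 10, 10),
                boundary = c("periodic", "reflective", "reflective"))
  r <- apply_boundary(c(10.3, 5, 5), c(1, 0, 0), u)
  expect_equal(r$pos[1, 1], 0.3)
  expect_equal(r$vel[1, 1], 1)          # periodic wrap keeps velocity
  r <- apply_boundary(c(5, -0.2, 5), c(0, -2, 0), u)
  expect_equal(r$pos[1, 2], 0.2)
  expect_equal(r$vel[1, 2], 2)          # reflective wall negates normal v
  r2 <- apply_boundary(r$pos, r$vel, u)
  expect_equal(r2$pos, r$pos)           # idempotent once in range
  expect_equal(r2$vel, r$vel)
})

test_that("universe invariants are enforced at construction", {
  expect_error(universe(dims = c(10, 10, 10), cutoff = 6,
                        boundary = "periodic"), "half the smallest")
  expect_silent(universe(dims = c(10, 10, 10), cutoff = 6,
                         boundary = "reflective"))
  expect_error(universe(dims = c(-1, 10, 10)), "positive")
})
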