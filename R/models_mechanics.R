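# Reusable mechanical model builders. These double as the synthetic-data
# layer for tests: every fixture is generated programmatically from a seed.

#' Two-particle harmonic oscillator
#'
#' Two Newtonian particles of mass `m` on the x axis, joined by a harmonic
#' bond `U = k (l - r0)^2`, stretched symmetrically by `displacement` about
#' the rest length. The analytic period of the relative coordinate is
#' `pi * sqrt(m / k)` (reduced mass `m/2`, effective stiffness `2k`).
#'
#' @param k,r0 bond stiffness and rest length
#' @param m particle mass
#' @param displacement initial stretch of the separation beyond `r0`
#' @param dt time step
#' @param seed RNG seed (the model is deterministic; the seed feeds streams)
#' @return a [universe]
#' @export
build_oscillator <- function(k = 1, r0 = 1, m = 1, displacement = 0.5,
                             dt = 0.005, seed = 1L) {
  u <- universe(dims = c(10, 10, 10), cutoff = 1, dt = dt,
                boundary = "reflective", seed = seed)
  register_type(u, particle_type("osc", mass = m, dynamics = "newtonian"))
  half <- (r0 + displacement) / 2
  ids <- create_particle(u, "osc", rbind(c(5 - half, 5, 5), c(5 + half, 5, 5)))
  add_bond(u, ids[1], ids[2], potential_harmonic(k, r0))
  u
}

#' Oscillator analytic period
#' @param k,m as in [build_oscillator()]
#' @return the two-body period `pi sqrt(m/k)`
#' @export
oscillator_period <- function(k = 1, m = 1) pi * sqrt(m / k)

#' Double pendulum under constant gravity
#'
#' A frozen pivot particle, two Newtonian bobs chained to it by stiff
#' harmonic bonds, and a constant downward explicit force on the bob type.
#' The bobs start horizontal, so the system swings under gravity while the
#' pivot never moves.
#'
#' @param g gravitational acceleration (force is `-m g` on z)
#' @param k,r0 bond stiffness and rest length
#' @param m bob mass
#' @param dt time step
#' @param seed RNG seed
#' @return a [universe]; particle ids 0 (pivot), 1 and 2 (bobs)
#' @export
build_pendulum <- function(g = 1, k = 100, r0 = 1, m = 1, dt = 0.002, seed = 1L) {
  u <- universe(dims = c(10, 10, 10), cutoff = 1, dt = dt,
                boundary = "reflective", seed = seed)
  register_type(u, particle_type("pivot", mass = 1, dynamics = "newtonian",
                                 frozen = TRUE))
  register_type(u, particle_type("bob", mass = m, dynamics = "newtonian"))
  pv <- create_particle(u, "pivot", c(5, 5, 8))
  b1 <- create_particle(u, "bob", c(5 + r0, 5, 8))
  b2 <- create_particle(u, "bob", c(5 + 2 * r0, 5, 8))
  pot <- potential_harmonic(k, r0)
  add_bond(u, pv, b1, pot)
  add_bond(u, b1, b2, pot)
  bind_force(u, "bob", force_constant(c(0, 0, -m * g)))
  u
}

# lattice points filling a ball, innermost first, lightly jittered: a
# uniform filling that relaxes quickly under the cell-cell potential
.ball_points <- function(n, spacing, jitter) {
  r_est <- spacing * (3 * n / (4 * pi * 0.64))^(1 / 3) + 2 * spacing
  g <- seq(-r_est, r_est, by = spacing)
  pts <- as.matrix(expand.grid(x = g, y = g, z = g))
  rad <- sqrt(rowSums(pts^2))
  pts <- pts[order(rad), , drop = FALSE][seq_len(n), , drop = FALSE]
  pts + matrix(stats::runif(3 * n, -jitter, jitter), n, 3)
}

#' Pre-assemble a relaxed spheroid of single-particle cells
#'
#' Cells (overdamped single particles) are placed uniformly in a ball and
#' relaxed under the cell-cell Morse potential until the largest
#' displacement per step falls below `tol`. Deterministic given `seed`.
#'
#' @param n_cells number of cells (>= 2)
#' @param seed RNG seed
#' @param d,a,r0 Morse well depth, inverse width and rest separation
#'   (defaults: `d = 0.1`, `a = 6`, `r0 = 1` cell diameter)
#' @param cutoff interaction cutoff (2 cell diameters)
#' @param tol convergence threshold on max per-step displacement
#' @param max_iter relaxation step budget (error if not converged)
#' @param dt relaxation time step
#' @return matrix of relaxed cell positions centered on the origin
#' @export
assemble_spheroid <- function(n_cells, seed = 1L, d = 0.1, a = 6, r0 = 1,
                              cutoff = 2, tol = 1e-3, max_iter = 3000,
                              dt = 0.01) {
  stopifnot(n_cells >= 2)
  box <- max(8, 2.5 * r0 * (n_cells)^(1 / 3) * 2) + 4
  u <- universe(dims = rep(box, 3), cutoff = cutoff, dt = dt,
                boundary = "reflective", seed = seed)
  register_type(u, particle_type("cell", mass = 1, radius = r0 / 2,
                                 dynamics = "overdamped"))
  pts <- with_stream(u, "model", .ball_points(n_cells, 0.95 * r0, 0.04 * r0))
  create_particle(u, "cell", sweep(pts, 2, rep(box / 2, 3), "+"))
  bind_potential(u, "cell", "cell",
                 potential_morse(d, a, r0, r_min = 0.85 * r0, r_max = cutoff))
  for (it in seq_len(max_iter)) {
    before <- positions(u)
    sim_step(u)
    disp <- sqrt(rowSums((positions(u) - before)^2))
    if (max(disp) < tol) {
      p <- positions(u)
      return(sweep(p, 2, colMeans(p)))
    }
  }
  stop(sprintf("spheroid relaxation did not converge in %d iterations", max_iter))
}

#' Two pre-assembled spheroids placed in close proximity
#'
#' Builds the fusion experiment: two relaxed spheroids of `n_per` cells
#' each, centers separated along x by twice their radius plus `gap`, with
#' the same single Morse cell-cell interaction. Fusion proceeds by
#' overdamped dynamics; the contact neck widens over time.
#'
#' @param n_per cells per spheroid
#' @param seed RNG seed
#' @param gap initial surface gap between the spheroids (negative values
#'   start them in slight contact, so the fusion neck exists at time zero)
#' @param dt time step for the fusion run
#' @inheritParams assemble_spheroid
#' @return a [universe]; `u$model$fusion` records the mid-plane x
#' @export
build_spheroid_fusion <- function(n_per = 500, seed = 1L, gap = -0.5,
                                  d = 0.1, a = 6, r0 = 1, cutoff = 2,
                                  dt = 0.02) {
  pts <- assemble_spheroid(n_per, seed = seed, d = d, a = a, r0 = r0,
                           cutoff = cutoff)
  rad <- max(sqrt(rowSums(pts^2)))
  sep <- 2 * rad + gap
  box_x <- 2 * sep + 8
  box_yz <- 4 * rad + 8
  u <- universe(dims = c(box_x, box_yz, box_yz), cutoff = cutoff, dt = dt,
                boundary = "reflective", seed = seed + 1L)
  register_type(u, particle_type("cell", mass = 1, radius = r0 / 2,
                                 dynamics = "overdamped"))
  cx <- box_x / 2; cyz <- box_yz / 2
  left <- sweep(pts, 2, c(cx - sep / 2, cyz, cyz), "+")
  right <- sweep(pts, 2, c(cx + sep / 2, cyz, cyz), "+")
  create_particle(u, "cell", rbind(left, right))
  bind_potential(u, "cell", "cell",
                 potential_morse(d, a, r0, r_min = 0.85 * r0, r_max = cutoff))
  u$model$fusion <- list(midplane = cx, radius = rad)
  u
}

#' Neck diameter of a fusing spheroid pair
#'
#' The largest extent along `axis` between any two particles lying within
#' the mid-plane slab `|x_mid - midplane_coord| <= slab_half_width` (for a
#' mid-plane normal along `mid_axis`). Returns 0 when fewer than two
#' particles lie in the slab.
#'
#' @param pos particle position matrix (n-by-3)
#' @param axis axis to measure along: `"x"`, `"y"` or `"z"`
#' @param midplane_coord mid-plane coordinate along `mid_axis`
#' @param slab_half_width half width of the slab
#' @param mid_axis mid-plane normal axis (the fusion axis)
#' @return the neck diameter (a length)
#' @export
neck_diameter <- function(pos, axis, midplane_coord, slab_half_width = 0.5,
                          mid_axis = "x") {
  ax <- match(axis, c("x", "y", "z"))
  mx <- match(mid_axis, c("x", "y", "z"))
  if (is.na(ax) || is.na(mx)) stop("axes must be 'x', 'y' or 'z'")
  slab <- abs(pos[, mx] - midplane_coord) <= slab_half_width
  if (sum(slab) < 2) return(0)
  max(pos[slab, ax]) - min(pos[slab, ax])
}

#' Run a fusion experiment, recording the neck diameter
#'
#' @param u universe from [build_spheroid_fusion()]
#' @param steps total steps
#' @param census_every record the metric every this many steps
#' @param slab_half_width half width of the mid-plane measurement slab
#'   (one cell diameter captures the full contact layer)
#' @return data.frame with `time`, `neck_y`, `neck_z`
#' @export
run_spheroid_fusion <- function(u, steps = 10000, census_every = 50,
                                slab_half_width = 1) {
  mid <- u$model$fusion$midplane
  n_rec <- floor(steps / census_every) + 1
  out <- data.frame(time = numeric(n_rec), neck_y = numeric(n_rec),
                    neck_z = numeric(n_rec))
  rec <- function(row) {
    p <- positions(u)
    out$time[row] <<- u$time
    out$neck_y[row] <<- neck_diameter(p, "y", mid, slab_half_width)
    out$neck_z[row] <<- neck_diameter(p, "z", mid, slab_half_width)
  }
  rec(1)
  for (b in seq_len(n_rec - 1)) {
    sim_step(u, census_every)
    rec(b + 1)
  }
  out
}

#' Membrane-separated compartments with an active species pump
#'
#' Two DPD fluid compartments separated by a deformable bonded membrane
#' sheet (periodic in-plane boundaries). One membrane-center particle is a
#' pump that actively moves the cargo species from lower-compartment fluid
#' particles through itself into upper-compartment fluid particles. Fickian
#' rules mix cargo within each compartment. The lower fluid starts with one
#' unit of cargo per particle.
#'
#' @param nx,ny membrane grid dimensions
#' @param n_fluid fluid particles per compartment
#' @param pump_k pump rate constant (0 disables the pump)
#' @param alpha,gamma,sigma,rc DPD parameters
#' @param seed RNG seed
#' @param dt time step
#' @return a [universe]
#' @export
build_membrane_pump <- function(nx = 6, ny = 6, n_fluid = 60, pump_k = 2,
                                alpha = 25, gamma = 4.5, sigma = 3, rc = 1,
                                seed = 1L, dt = 0.01) {
  lz <- 12
  u <- universe(dims = c(nx, ny, lz), cutoff = max(rc, 1), dt = dt,
                boundary = c("periodic", "periodic", "reflective"),
                seed = seed)
  register_type(u, particle_type("memb", mass = 1, dynamics = "newtonian"))
  register_type(u, particle_type("pump", mass = 1, dynamics = "newtonian",
                                 species = "cargo"))
  register_type(u, particle_type("fluid_lo", mass = 1, dynamics = "newtonian",
                                 species = "cargo"))
  register_type(u, particle_type("fluid_up", mass = 1, dynamics = "newtonian",
                                 species = "cargo"))
  zmid <- lz / 2
  grid <- as.matrix(expand.grid(x = seq_len(nx) - 0.5, y = seq_len(ny) - 0.5))
  centre <- which.min((grid[, 1] - nx / 2)^2 + (grid[, 2] - ny / 2)^2)
  mids <- integer(nrow(grid))
  for (q in seq_len(nrow(grid))) {
    tp <- if (q == centre) "pump" else "memb"
    mids[q] <- create_particle(u, tp, c(grid[q, 1], grid[q, 2], zmid))
  }
  sheet_pot <- potential_harmonic(20, 1)
  idx <- function(i, j) mids[((j - 1) %% ny) * nx + ((i - 1) %% nx) + 1]
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    add_bond(u, idx(i, j), idx(i + 1, j), sheet_pot)
    add_bond(u, idx(i, j), idx(i, j + 1), sheet_pot)
  }
  lo <- with_stream(u, "model", cbind(stats::runif(n_fluid, 0, nx),
                                      stats::runif(n_fluid, 0, ny),
                                      stats::runif(n_fluid, 1, zmid - 0.4)))
  up <- with_stream(u, "model", cbind(stats::runif(n_fluid, 0, nx),
                                      stats::runif(n_fluid, 0, ny),
                                      stats::runif(n_fluid, zmid + 0.4, lz - 1)))
  lo_ids <- create_particle(u, "fluid_lo", lo)
  create_particle(u, "fluid_up", up)
  dpd <- potential_dpd(alpha, gamma, sigma, rc)
  tn <- c("memb", "pump", "fluid_lo", "fluid_up")
  for (i in seq_along(tn)) for (j in i:length(tn)) {
    bind_potential(u, tn[i], tn[j], dpd)
  }
  add_flux_rule(u, "cargo", "fluid_lo", "fluid_lo", "fick", k = 1, r_cutoff = rc)
  add_flux_rule(u, "cargo", "fluid_up", "fluid_up", "fick", k = 1, r_cutoff = rc)
  if (pump_k > 0) {
    add_flux_rule(u, "cargo", "fluid_lo", "pump", "pump", k = pump_k,
                  r_cutoff = rc, direction = "a_to_b")
    add_flux_rule(u, "cargo", "pump", "fluid_up", "pump", k = pump_k,
                  r_cutoff = rc, direction = "a_to_b")
  }
  set_species(u, lo_ids, "cargo", 1)
  u
}

#' Total cargo by compartment
#' @param u universe from [build_membrane_pump()]
#' @return named list `lower`, `upper`, `pump`, `total`
#' @export
compartment_totals <- function(u) {
  tot <- function(tp) {
    ids <- particle_ids(u, tp)
    if (!length(ids)) 0 else sum(get_species(u, ids, "cargo"))
  }
  lower <- tot("fluid_lo"); upper <- tot("fluid_up"); pump <- tot("pump")
  list(lower = lower, upper = upper, pump = pump,
       total = lower + upper + pump)
}
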