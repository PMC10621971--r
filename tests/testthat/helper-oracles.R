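# Independent oracles used across the suite. These deliberately avoid the
# package's cell-list machinery: distances and forces are recomputed from
# first principles with dense O(N^2) scans.

# minimum-image displacement matrix oracle (independent of min_image())
mi_disp <- function(from, to, dims, boundary) {
  d <- to - from
  for (ax in 1:3) {
    if (boundary[ax] == "periodic") {
      d[ax] <- d[ax] - dims[ax] * round(d[ax] / dims[ax])
    }
  }
  d
}

# dense all-pairs force/energy oracle for a single pair potential bound to
# every particle pair (strict r < cutoff), returning forces and energy
brute_forces <- function(pos, dims, boundary, cutoff, u_fn, du_fn,
                         r_max = cutoff) {
  n <- nrow(pos)
  f <- matrix(0, n, 3)
  pe <- 0
  rmax <- min(r_max, cutoff)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- mi_disp(pos[i, ], pos[j, ], dims, boundary)
      r <- sqrt(sum(d^2))
      if (r < rmax) {
        fi <- (du_fn(r) / r) * d
        f[i, ] <- f[i, ] + fi
        f[j, ] <- f[j, ] - fi
        pe <- pe + u_fn(r)
      }
    }
  }
  list(force = f, energy = pe)
}

# dense neighbor scan oracle
brute_neighbors <- function(pos, idx, dims, boundary, distance) {
  hits <- integer(0)
  for (j in seq_len(nrow(pos))) {
    if (j == idx) next
    d <- mi_disp(pos[idx, ], pos[j, ], dims, boundary)
    if (sum(d^2) <= distance^2) hits <- c(hits, j)
  }
  hits
}

# numerical gradient of a scalar function of an n-by-3 coordinate matrix
num_grad <- function(f, X, h = 1e-6) {
  g <- array(0, dim(X))
  for (i in seq_len(nrow(X))) {
    for (j in 1:3) {
      Xp <- X; Xp[i, j] <- Xp[i, j] + h
      Xm <- X; Xm[i, j] <- Xm[i, j] - h
      g[i, j] <- (f(Xp) - f(Xm)) / (2 * h)
    }
  }
  g
}

# one FTCS step of the 2D heat equation with zero-flux boundaries
ftcs_step <- function(f, D, dt, h = 1) {
  nx <- nrow(f); ny <- ncol(f)
  up <- rbind(f[1, , drop = FALSE], f[-nx, ])
  dn <- rbind(f[-1, ], f[nx, , drop = FALSE])
  lf <- cbind(f[, 1, drop = FALSE], f[, -ny])
  rt <- cbind(f[, -1], f[, ny, drop = FALSE])
  f + D * dt / h^2 * ((up - f) + (dn - f) + (lf - f) + (rt - f))
}

# a universe of N randomly placed particles of one Newtonian type
random_universe <- function(n, dims, cutoff, boundary, seed, dt = 0.01,
                            vel_sd = 0) {
  u <- universe(dims = dims, cutoff = cutoff, dt = dt, boundary = boundary,
                seed = seed)
  register_type(u, particle_type("A", mass = 1, dynamics = "newtonian"))
  set.seed(seed * 101 + 7)
  pos <- cbind(runif(n, 0, dims[1]), runif(n, 0, dims[2]), runif(n, 0, dims[3]))
  vel <- matrix(stats::rnorm(3 * n, 0, vel_sd), n, 3)
  create_particle(u, "A", pos, vel)
  u
}

# a small molecule-like fixture: a chain of bonded particles with angle and
# dihedral terms (assembled programmatically)
toy_molecule <- function(seed = 1, n = 6, dt = 0.002) {
  u <- universe(dims = c(20, 20, 20), cutoff = 2, dt = dt,
                boundary = "reflective", seed = seed)
  register_type(u, particle_type("atom", mass = 1, dynamics = "newtonian"))
  set.seed(seed)
  base <- c(8, 10, 10)
  pos <- t(vapply(seq_len(n), function(i) {
    base + c(i * 1.1, 0.4 * sin(i), 0.3 * cos(i)) + runif(3, -0.05, 0.05)
  }, numeric(3)))
  ids <- create_particle(u, "atom", pos)
  bp <- potential_harmonic(20, 1.1)
  ap <- potential_harmonic(3, 1.9)
  dp <- potential_harmonic(0.5, 0.5, r_min = -pi)
  for (i in seq_len(n - 1)) add_bond(u, ids[i], ids[i + 1], bp)
  for (i in seq_len(n - 2)) add_angle(u, ids[i], ids[i + 1], ids[i + 2], ap)
  for (i in seq_len(n - 3)) add_dihedral(u, ids[i], ids[i + 1], ids[i + 2],
                                         ids[i + 3], dp)
  u
}
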