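# Delta-Notch lateral inhibition on a sheet of cells, after the classic
# two-variable ODE model of contact-mediated inhibition: Notch activity n
# is driven by the mean Delta level of contacting neighbors, and Delta
# production is inhibited by the cell's own Notch activity. On a lattice
# this produces alternating high/low Delta patterns (anti-correlated
# neighbors). An optional diffusing signal gates the dynamics, so
# patterning spreads as a front from a source edge.

#' Parameters of the lateral-inhibition ODE model
#'
#' `dn/dt = F(Dbar) - n` with `F(x) = x^k / (a + x^k)`;
#' `dd/dt = v (G(n) - d)` with `G(n) = 1 / (1 + b n^h)`;
#' `Dbar` is the mean Delta over neighbors within `coupling` distance.
#'
#' @param a activation constant of Notch by neighbor Delta (> 0)
#' @param b inhibition constant of Delta by Notch (> 0)
#' @param k,h Hill exponents (> 0)
#' @param v ratio of Delta to Notch kinetic rates (> 0)
#' @param coupling neighbor radius defining "contact" between cell centers
#' @return parameter list
#' @export
collier_params <- function(a = 0.01, b = 100, k = 2, h = 2, v = 1,
                           coupling = 1.1) {
  stopifnot(a > 0, b > 0, k > 0, h > 0, v > 0, coupling > 0)
  list(a = a, b = b, k = k, h = h, v = v, coupling = coupling)
}

#' Right-hand side of the lateral-inhibition ODEs
#'
#' @param n,d Notch and Delta levels (nonnegative, vectorized)
#' @param dbar mean neighbor Delta level(s)
#' @param params from [collier_params()]
#' @return list with `dn` and `dd`
#' @export
collier_rhs <- function(n, d, dbar, params) {
  if (any(n < 0) || any(d < 0) || any(dbar < 0)) {
    stop("Notch/Delta states must be nonnegative")
  }
  f <- dbar^params$k / (params$a + dbar^params$k)
  g <- 1 / (1 + params$b * n^params$h)
  list(dn = f - n, dd = params$v * (g - d))
}

#' Homogeneous fixed point of the lateral-inhibition model
#'
#' Solves `n = F(G(n))` (uniform states, `Dbar = d`) by root finding.
#'
#' @param params from [collier_params()]
#' @return list with `n` and `d` at the uniform equilibrium
#' @export
collier_fixed_point <- function(params) {
  fn <- function(n) {
    g <- 1 / (1 + params$b * n^params$h)
    g^params$k / (params$a + g^params$k) - n
  }
  n_star <- stats::uniroot(fn, c(1e-12, 1), tol = 1e-14)$root
  d_star <- 1 / (1 + params$b * n_star^params$h)
  list(n = n_star, d = d_star)
}

# reaction callback integrating the ODEs on every sheet cell; the mean
# neighbor Delta comes from the current step's in-cutoff pair list
.dn_reaction <- function(state, dt_sub, u, ids) {
  p <- u$model$dn$params
  inc <- matrix(0, nrow(state), ncol(state))
  colnames(inc) <- colnames(state)
  pairs <- u$.pairs
  slots <- .slot_of(u, ids)
  dcol <- match("delta", u$species)
  dbar <- numeric(length(ids))
  if (!is.null(pairs) && length(pairs$ii)) {
    sel <- which(pairs$r <= p$coupling)
    if (length(sel)) {
      ii <- pairs$ii[sel]; jj <- pairs$jj[sel]
      dsum <- rowsum(c(u$state[jj, dcol], u$state[ii, dcol]), c(ii, jj),
                     reorder = TRUE)
      cnt <- rowsum(rep(1, 2 * length(sel)), c(ii, jj), reorder = TRUE)
      idx <- match(slots, as.integer(rownames(dsum)))
      got <- !is.na(idx)
      dbar[got] <- dsum[idx[got], 1] / cnt[idx[got], 1]
    }
  }
  rhs <- collier_rhs(state[, "notch"], state[, "delta"], dbar, p)
  gate <- 1
  if (isTRUE(u$model$dn$gated)) {
    s <- state[, "signal"]
    gate <- s^2 / (u$model$dn$gate_k^2 + s^2)
  }
  inc[, "notch"] <- gate * rhs$dn * dt_sub
  inc[, "delta"] <- gate * rhs$dd * dt_sub
  inc
}

# clamps the signal species to 1 on the source-edge cells
.dn_source_event <- function(u, time) {
  set_species(u, u$model$dn$source_ids, "signal", 1)
  invisible(NULL)
}

#' Build a Delta-Notch sheet
#'
#' A hexagonally packed sheet of `nx` by `ny` static cells (frozen
#' particles; signaling, not mechanics, is the model) carrying `notch`,
#' `delta` and `signal` species. States start at the homogeneous fixed
#' point perturbed by uniform noise of amplitude `perturb`. With
#' `gated = TRUE`, the ODEs are multiplied by a Hill gate on the local
#' `signal` level, the source edge (lowest row) is clamped to signal 1,
#' and a Fickian rule diffuses the signal cell to cell, so patterning
#' spreads from the source edge.
#'
#' @param nx,ny sheet dimensions (cells)
#' @param spacing center-to-center neighbor distance
#' @param params from [collier_params()]
#' @param perturb amplitude of the initial uniform perturbation
#' @param gated enable signal-gated induction
#' @param signal_D diffusivity of the gating signal (gated mode)
#' @param gate_k half-activation signal level of the gate
#' @param seed RNG seed
#' @param dt time step
#' @return a [universe]; `u$model$dn` records ids, rows and parameters
#' @export
build_delta_notch <- function(nx = 12, ny = 12, spacing = 1,
                              params = collier_params(), perturb = 0.05,
                              gated = FALSE, signal_D = 0.5, gate_k = 0.2,
                              seed = 1L, dt = 0.05) {
  row_h <- spacing * sqrt(3) / 2
  u <- universe(dims = c(nx * spacing + 4, ny * row_h + 4, 4),
                cutoff = 1.2 * spacing, dt = dt, boundary = "reflective",
                seed = seed, confine_axis = 3L)
  register_type(u, particle_type("dncell", mass = 1, dynamics = "overdamped",
                                 species = c("notch", "delta", "signal"),
                                 frozen = TRUE))
  xs <- ys <- rows <- numeric(0)
  for (j in seq_len(ny)) {
    xx <- (seq_len(nx) - 1) * spacing + ifelse(j %% 2 == 0, spacing / 2, 0) + 2
    xs <- c(xs, xx)
    ys <- c(ys, rep((j - 1) * row_h + 2, nx))
    rows <- c(rows, rep(j, nx))
  }
  ids <- create_particle(u, "dncell", cbind(xs, ys, 2))
  fp <- collier_fixed_point(params)
  nn <- length(ids)
  eps <- with_stream(u, "model",
                     matrix(stats::runif(2 * nn, -perturb, perturb), nn, 2))
  set_species(u, ids, "notch", pmax(0, fp$n * (1 + eps[, 1])))
  set_species(u, ids, "delta", pmax(0, fp$d * (1 + eps[, 2])))
  u$model$dn <- list(params = params, ids = ids, rows = rows,
                     gated = gated, gate_k = gate_k, fixed_point = fp,
                     source_ids = ids[rows == 1])
  add_reaction(u, "dncell", .dn_reaction, name = "dn_reaction")
  if (gated) {
    k_sig <- flux_constant_from_diffusivity(signal_D, spacing, 1.2 * spacing)
    add_flux_rule(u, "signal", "dncell", "dncell", "fick", k = k_sig,
                  r_cutoff = 1.2 * spacing)
    register_event(u, .dn_source_event, period_steps = 1L, name = "dn_source")
  }
  u
}

#' Neighbor Delta correlation of a sheet
#'
#' Pearson correlation of Delta levels over all contacting (in-coupling)
#' cell pairs, both orientations; lateral inhibition drives it negative.
#'
#' @param u universe from [build_delta_notch()]
#' @return correlation coefficient
#' @export
neighbor_delta_correlation <- function(u) {
  p <- u$model$dn$params
  ids <- u$model$dn$ids
  slots <- .slot_of(u, ids)
  pos <- u$pos[slots, , drop = FALSE]
  d <- u$state[slots, match("delta", u$species)]
  n <- length(ids)
  di <- numeric(0); dj <- numeric(0)
  for (i in seq_len(n - 1)) {
    dx <- pos[(i + 1):n, 1] - pos[i, 1]
    dy <- pos[(i + 1):n, 2] - pos[i, 2]
    nb <- which(dx^2 + dy^2 <= p$coupling^2)
    if (length(nb)) {
      di <- c(di, rep(d[i], length(nb)))
      dj <- c(dj, d[i + nb])
    }
  }
  stats::cor(c(di, dj), c(dj, di))
}

#' Time for each cell to develop a local pattern
#'
#' Runs a gated sheet and records, per cell, the first time its Delta level
#' deviates from the initial uniform equilibrium by more than `threshold`
#' (relative to the equilibrium span). Cells that never cross within the
#' run get NA.
#'
#' @param u universe from [build_delta_notch()] (typically `gated = TRUE`)
#' @param steps steps to run
#' @param check_every census interval in steps
#' @param threshold absolute Delta deviation defining "patterned"
#' @return data.frame with `id`, `row` (distance rank from the source
#'   edge), `t_pattern`
#' @export
time_to_pattern <- function(u, steps = 4000, check_every = 10,
                            threshold = 0.25) {
  dnm <- u$model$dn
  ids <- dnm$ids
  d0 <- dnm$fixed_point$d
  t_pat <- rep(NA_real_, length(ids))
  n_checks <- floor(steps / check_every)
  for (b in seq_len(n_checks)) {
    sim_step(u, check_every)
    d <- get_species(u, ids, "delta")
    hit <- is.na(t_pat) & abs(d - d0) > threshold
    t_pat[hit] <- u$time
  }
  data.frame(id = ids, row = dnm$rows, t_pattern = t_pat)
}

#' Static diffusion grid carrying a regulatory signal
#'
#' A uniform rectangular grid of frozen particles representing point
#' measurements of a concentration field. The flux constant is derived from
#' the diffusivity `D` via the grid-equivalence relation, and the flux
#' cutoff lies between the grid spacing and the diagonal, so the particle
#' transport performs exactly the first-order central finite-difference
#' (FTCS) computation of the diffusion equation with zero-flux boundaries.
#' With `source_edge = TRUE`, the first grid row is clamped to signal 1
#' each step.
#'
#' @param nx,ny grid dimensions
#' @param spacing grid spacing `h`
#' @param D diffusion coefficient
#' @param source_edge clamp the first row to 1
#' @param seed RNG seed
#' @param dt time step
#' @return a [universe]; `u$model$grid` records ids and layout
#' @export
build_signal_grid <- function(nx = 32, ny = 32, spacing = 1, D = 0.1,
                              source_edge = FALSE, seed = 1L, dt = 0.1) {
  rc <- 1.4 * spacing     # spacing < rc < diagonal: 4-neighbor stencil
  u <- universe(dims = c(nx * spacing + 2, ny * spacing + 2, 4),
                cutoff = rc, dt = dt, boundary = "reflective", seed = seed,
                confine_axis = 3L)
  register_type(u, particle_type("gridpt", mass = 1, dynamics = "overdamped",
                                 species = "signal", frozen = TRUE))
  xs <- rep((seq_len(nx) - 1) * spacing + 1, ny)
  ys <- rep((seq_len(ny) - 1) * spacing + 1, each = nx)
  ids <- create_particle(u, "gridpt", cbind(xs, ys, 2))
  k <- flux_constant_from_diffusivity(D, spacing, rc)
  add_flux_rule(u, "signal", "gridpt", "gridpt", "fick", k = k, r_cutoff = rc)
  u$model$grid <- list(ids = ids, nx = nx, ny = ny, spacing = spacing, D = D,
                       source_ids = ids[seq_len(nx)])
  if (source_edge) {
    register_event(u, .grid_source_event, period_steps = 1L,
                   name = "signal_grid_source")
  }
  u
}

.grid_source_event <- function(u, time) {
  set_species(u, u$model$grid$source_ids, "signal", 1)
  invisible(NULL)
}

#' Local signal concentration near a point
#'
#' Read-only query coupling grid fields to cell models: the mean signal of
#' grid particles within `radius` of `point`.
#'
#' @param u universe containing a signal grid
#' @param point 3-vector
#' @param radius query radius
#' @return mean signal (0 if no grid particle is in range)
#' @export
local_signal <- function(u, point, radius) {
  slots <- .live_slots(u, "gridpt")
  d <- min_image(matrix(point, length(slots), 3, byrow = TRUE),
                 u$pos[slots, , drop = FALSE], u)
  sel <- rowSums(d * d) <= radius^2
  if (!any(sel)) return(0)
  mean(u$state[slots[sel], match("signal", u$species)])
}
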