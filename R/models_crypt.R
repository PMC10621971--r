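# Colonic-crypt agent-based model. The crypt is unfolded onto a plane:
# periodic boundaries along the horizontal axis, a reflective floor, and a
# removal boundary ("the base") at the top edge. Each cell is an overdamped
# particle carrying a cell-cycle state machine (G1 -> S -> G2 -> M ->
# division -> G1) with a per-cell G1 duration drawn from a truncated normal
# distribution. Cycling only occurs for cells deep enough in the crypt
# (below the proliferative-zone boundary). Each founder cell carries a
# unique clone id copied to all progeny; under division, displacement and
# removal the population drifts toward monoclonality.

.crypt_defaults <- function() {
  list(width = 20, height = 10, prolif_frac = 2 / 3,
       g1_mean = 2, g1_sd = 0.5, s_dur = 1, g2_dur = 1, m_dur = 1,
       daughter_offset = 0.1,
       morse_d = 0.2, morse_a = 5, morse_r0 = 1, cutoff = 1.5, dt = 0.015,
       step_cap = 0.1, ci_neighbors = 6, ci_radius = 1.1, motility = 0.01)
}

#' One cell-cycle bookkeeping step (pure rule)
#'
#' Vectorized core of the crypt step rule: given phases (1 = G1, 2 = S,
#' 3 = G2, 4 = M), remaining phase times and vertical coordinates, returns
#' the decremented clocks and the action masks. Clocks only run for cells
#' within the proliferative zone (`y < prolif_frac * height`); expiry of M
#' emits a division; reaching the base (`y >= height`) emits a removal.
#'
#' @param phase integer vector of phases
#' @param remaining remaining time in the current phase
#' @param y vertical coordinates
#' @param dt elapsed time
#' @param geom list with `height` and `prolif_frac`
#' @param crowded optional logical mask of contact-inhibited cells (their
#'   cycle clock pauses)
#' @return list `remaining` (decremented), `advance`, `divide`, `remove`
#'   (logical masks; `divide` implies leaving M, `advance` any other expiry)
#' @export
crypt_cell_actions <- function(phase, remaining, y, dt, geom, crowded = FALSE) {
  prolif <- y < geom$prolif_frac * geom$height & !crowded
  rem <- remaining - ifelse(prolif, dt, 0)
  expired <- prolif & rem <= 0
  list(remaining = rem,
       advance = expired & phase < 4L,
       divide = expired & phase == 4L,
       remove = y >= geom$height)
}

.crypt_draw_g1 <- function(u, n, p) {
  pmax(0, with_stream(u, "events", stats::rnorm(n, p$g1_mean, p$g1_sd)))
}

.crypt_phase_duration <- function(u, phase, p) {
  # durations for phases entered; G1 durations are random per cell
  out <- numeric(length(phase))
  out[phase == 2L] <- p$s_dur
  out[phase == 3L] <- p$g2_dur
  out[phase == 4L] <- p$m_dur
  g1 <- which(phase == 1L)
  if (length(g1)) out[g1] <- .crypt_draw_g1(u, length(g1), p)
  out
}

# event callback: advance every cell's cycle, divide, remove
.crypt_event <- function(u, time) {
  cs <- u$model$crypt
  p <- cs$params
  ids <- particle_ids(u)
  if (!length(ids)) return(invisible(NULL))
  slots <- .slot_of(u, ids)
  # contact inhibition: the cycle pauses for cells packed beyond a
  # neighbor-count threshold, which caps tissue density
  crowded <- FALSE
  pairs <- u$.pairs
  if (!is.null(pairs) && length(pairs$ii)) {
    sel <- which(pairs$r <= p$ci_radius)
    nb <- integer(u$cap)
    if (length(sel)) {
      cnt <- rowsum(rep(1L, 2L * length(sel)),
                    c(pairs$ii[sel], pairs$jj[sel]), reorder = TRUE)
      nb[as.integer(rownames(cnt))] <- cnt[, 1]
    }
    crowded <- nb[slots] > p$ci_neighbors
  }
  act <- crypt_cell_actions(cs$phase[ids + 1L], cs$remaining[ids + 1L],
                            u$pos[slots, 2], u$dt,
                            list(height = p$height, prolif_frac = p$prolif_frac),
                            crowded = crowded)
  cs$remaining[ids + 1L] <- act$remaining
  adv <- ids[act$advance]
  if (length(adv)) {
    newp <- cs$phase[adv + 1L] + 1L
    cs$phase[adv + 1L] <- newp
    cs$remaining[adv + 1L] <- .crypt_phase_duration(u, newp, p)
  }
  div <- ids[act$divide]
  for (id in div) {
    # parent re-enters G1; daughter adjacent at a small random planar offset
    cs$phase[id + 1L] <- 1L
    cs$remaining[id + 1L] <- .crypt_draw_g1(u, 1L, p)
    ang <- with_stream(u, "events", stats::runif(1, 0, 2 * pi))
    off <- p$daughter_offset * c(cos(ang), sin(ang), 0)
    pos <- u$pos[.slot_of(u, id), ] + off
    did <- create_particle(u, "cell", pos)
    ng1 <- .crypt_draw_g1(u, 1L, p)
    cs$phase <- .grow_to(cs$phase, did + 1L, 1L)
    cs$remaining <- .grow_to(cs$remaining, did + 1L, ng1)
    cs$clone <- .grow_to(cs$clone, did + 1L, cs$clone[id + 1L])
  }
  rem <- ids[act$remove]
  if (length(rem)) destroy_particle(u, rem)
  u$model$crypt <- cs
  invisible(NULL)
}

.grow_to <- function(v, idx, value) {
  if (idx > length(v)) v <- c(v, rep(NA, idx - length(v)))
  v[idx] <- value
  v
}

#' Build the crypt model
#'
#' @param n_initial number of founder cells (each with a unique clone id)
#' @param seed RNG seed
#' @param params optional overrides of the model defaults (domain 20 x 10
#'   cell diameters, proliferative zone = lower 2/3, G1 ~ N(2, 0.5)
#'   truncated at 0, S = G2 = M = 1 time unit, daughter offset 0.1, Morse
#'   cell-cell mechanics)
#' @return a [universe] with the crypt event registered
#' @export
build_crypt <- function(n_initial = 200, seed = 0L, params = list()) {
  p <- utils::modifyList(.crypt_defaults(), params)
  u <- universe(dims = c(p$width, p$height + 3, 4), cutoff = p$cutoff,
                dt = p$dt, boundary = c("periodic", "reflective", "reflective"),
                seed = seed, confine_axis = 3L, overdamped_cap = p$step_cap)
  register_type(u, particle_type("cell", mass = 1, radius = 0.5,
                                 dynamics = "overdamped"))
  bind_potential(u, "cell", "cell",
                 potential_morse(p$morse_d, p$morse_a, p$morse_r0,
                                 r_min = 0.8 * p$morse_r0, r_max = p$cutoff))
  # stochastic cell motility: thermal-like kicks with effective energy
  # `motility`, giving overdamped cells a diffusive random walk that drives
  # neutral drift of the clonal composition
  if (p$motility > 0) {
    bind_force(u, "cell", force_langevin(1, p$motility))
  }
  # founders on a jittered lattice filling the crypt
  ncol_ <- ceiling(sqrt(n_initial * p$width / p$height))
  nrow_ <- ceiling(n_initial / ncol_)
  gx <- (rep(seq_len(ncol_), nrow_) - 0.5) * p$width / ncol_
  gy <- (rep(seq_len(nrow_), each = ncol_) - 0.5) * p$height / nrow_
  keep <- seq_len(n_initial)
  jit <- with_stream(u, "model",
                     matrix(stats::runif(2 * n_initial, -0.05, 0.05), n_initial, 2))
  pos <- cbind(gx[keep] + jit[, 1], gy[keep] + jit[, 2], 2)
  ids <- create_particle(u, "cell", pos)
  # desynchronized starting phases: uniform position within a mean cycle
  cycle <- c(p$g1_mean, p$s_dur, p$g2_dur, p$m_dur)
  ph <- with_stream(u, "model", sample.int(4L, n_initial, replace = TRUE,
                                           prob = cycle / sum(cycle)))
  rem <- with_stream(u, "model", stats::runif(n_initial)) * cycle[ph]
  cs <- list(params = p,
             phase = .grow_to(integer(0), max(ids) + 1L, 0L),
             remaining = .grow_to(numeric(0), max(ids) + 1L, 0),
             clone = .grow_to(integer(0), max(ids) + 1L, 0L))
  cs$phase[ids + 1L] <- ph
  cs$remaining[ids + 1L] <- rem
  cs$clone[ids + 1L] <- seq_along(ids) - 1L
  u$model$crypt <- cs
  register_event(u, .crypt_event, period_steps = 1L, name = "crypt_step")
  u
}

#' Number of distinct clones among live cells
#' @param u universe from [build_crypt()]
#' @return integer clone count
#' @export
count_clones <- function(u) {
  ids <- particle_ids(u)
  if (!length(ids)) return(0L)
  length(unique(u$model$crypt$clone[ids + 1L]))
}

#' Run a crypt replicate, recording a clone census
#'
#' @param n_initial founder cells
#' @param seed replicate seed
#' @param horizon simulated time to cover
#' @param census_every census interval in time units
#' @param params model overrides passed to [build_crypt()]
#' @return data.frame with `time`, `n_cells`, `n_clones`
#' @export
run_crypt <- function(n_initial = 200, seed = 0L, horizon = 60,
                      census_every = 1, params = list()) {
  u <- build_crypt(n_initial, seed = seed, params = params)
  steps_per <- max(1L, round(census_every / u$dt))
  n_census <- floor(horizon / census_every)
  out <- data.frame(time = numeric(n_census + 1),
                    n_cells = integer(n_census + 1),
                    n_clones = integer(n_census + 1))
  out$time[1] <- 0; out$n_cells[1] <- particle_count(u)
  out$n_clones[1] <- count_clones(u)
  for (b in seq_len(n_census)) {
    sim_step(u, steps_per)
    out$time[b + 1] <- u$time
    out$n_cells[b + 1] <- particle_count(u)
    out$n_clones[b + 1] <- count_clones(u)
  }
  out
}
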