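# The simulation loop. Each step performs three stages:
#   Prep   - reset force accumulators and cached energies;
#   Force  - enumerate in-cutoff pairs via the cell grid, apply every bound
#            implicit potential (scoped by cluster mode), bonded terms and
#            explicit forces, and evaluate species transport fluxes;
#   Update - integrate particle trajectories (explicit first-order forward
#            time integration), apply boundary conditions, re-index cells,
#            cull dissociated bonded items, integrate species in
#            sub-intervals, and dispatch due events.

.accum_force <- function(u, slots, f) {
  for (ax in 1:3) {
    s <- rowsum(f[, ax], slots, reorder = TRUE)
    idx <- as.integer(rownames(s))
    u$force[idx, ax] <- u$force[idx, ax] + s[, 1]
  }
}

#' Compute all forces (the Force stage)
#'
#' Fills the per-particle force accumulators from every bound implicit
#' potential, all bonded interactions and all explicit forces, and returns
#' the total potential energy (each pair counted once). Pair forces are
#' applied equal-and-opposite by construction; frozen particles accumulate
#' forces like any other (they simply skip integration).
#'
#' Normally called from [sim_step()] after the Prep stage has zeroed the
#' accumulators; callable directly for inspection.
#'
#' @param u a [universe]
#' @param pairs optional precomputed pair list (from the cell grid)
#' @return total potential energy (implicit + bonded)
#' @export
compute_forces <- function(u, pairs = NULL) {
  if (is.null(pairs)) pairs <- enumerate_pairs(u)
  u$.pairs <- pairs
  pe <- 0
  if (length(pairs$ii) && length(u$bindings)) {
    ti <- u$type_id[pairs$ii]; tj <- u$type_id[pairs$jj]
    tci <- u$top_cluster[pairs$ii]; tcj <- u$top_cluster[pairs$jj]
    same_cluster <- !is.na(tci) & !is.na(tcj) & tci == tcj
    for (bind in u$bindings) {
      mask <- (ti == bind$a & tj == bind$b) | (ti == bind$b & tj == bind$a)
      if (bind$mode == "bound") mask <- mask & same_cluster
      else if (bind$mode == "unbound") mask <- mask & !same_cluster
      if (!any(mask)) next
      for (leaf in bind$leaves) {
        rmax_eff <- min(leaf$r_max, u$cutoff)
        sel <- which(mask & pairs$r < rmax_eff)
        if (!length(sel)) next
        r <- pairs$r[sel]
        dvec <- cbind(pairs$dx[sel], pairs$dy[sel], pairs$dz[sel])  # i -> j
        if (leaf$kind == "dpd") {
          p <- leaf$params
          w <- 1 - r / p$rc
          e <- -dvec / r                  # unit vector j -> i
          v_rel <- u$vel[pairs$ii[sel], , drop = FALSE] -
                   u$vel[pairs$jj[sel], , drop = FALSE]
          fmag <- p$alpha * w -
            p$gamma * w^2 * (e[, 1] * v_rel[, 1] + e[, 2] * v_rel[, 2] + e[, 3] * v_rel[, 3])
          if (p$sigma > 0) {
            xi <- with_stream(u, "engine", stats::rnorm(length(sel)))
            fmag <- fmag + p$sigma * w * xi / sqrt(u$dt)
          }
          f_i <- fmag * e
          pe <- pe + sum(p$alpha * p$rc / 2 * w^2)
        } else {
          ev <- evaluate_pair(leaf, r)
          f_i <- (ev$dudr / r) * dvec     # = -dU/dr * (r_i - r_j)/r
          pe <- pe + sum(ev$energy)
        }
        .accum_force(u, c(pairs$ii[sel], pairs$jj[sel]), rbind(f_i, -f_i))
      }
    }
  }
  pe <- pe + accumulate_bonded(u)
  # explicit forces
  for (ex in u$explicit) {
    slots <- .live_slots(u)
    slots <- slots[u$type_id[slots] == ex$type]
    if (!length(slots)) next
    f <- ex$force
    add <- switch(f$kind,
      constant = matrix(f$f0, length(slots), 3, byrow = TRUE),
      friction = -f$gamma * u$vel[slots, , drop = FALSE],
      langevin = {
        amp <- sqrt(2 * f$gamma * f$kbt / u$dt)
        with_stream(u, "engine",
                    matrix(stats::rnorm(3 * length(slots)), length(slots), 3)) * amp
      },
      custom = {
        m <- f$fn(u, u$id[slots])
        if (!is.matrix(m) || nrow(m) != length(slots) || ncol(m) != 3) {
          stop("custom explicit force callback must return an n-by-3 matrix")
        }
        m
      })
    u$force[slots, ] <- u$force[slots, ] + add
  }
  u$potential_energy <- pe
  pe
}

#' Advance the simulation by one step (or several)
#'
#' Performs the Prep, Force and Update stages. Integration is explicit
#' first-order forward: Newtonian particles use the semi-implicit
#' (velocity-first) update `v <- v + (f/m) dt; r <- r + v dt`; overdamped
#' particles move as `r <- r + (f/m) dt` with `m` the drag coefficient.
#' Frozen particles accumulate forces but never move. Due events fire at the
#' end of the Update stage (after integration and species transport), in
#' registration order, on steps where `step_count %% period == 0`.
#'
#' @param u a [universe]
#' @param n number of steps
#' @return the universe, invisibly
#' @export
sim_step <- function(u, n = 1L) {
  for (s in seq_len(n)) {
    # ---- Prep ----
    u$force[] <- 0
    # ---- Force ----
    pairs <- enumerate_pairs(u)
    compute_forces(u, pairs)
    # ---- Update ----
    live <- .live_slots(u)
    moving <- live[!u$frozen[live]]
    if (u$confine_axis > 0) {
      u$force[, u$confine_axis] <- 0
      u$vel[, u$confine_axis] <- 0
    }
    if (length(moving)) {
      dyn <- .dynamics_of(u, moving)
      newt <- moving[dyn == "newtonian"]
      over <- moving[dyn == "overdamped"]
      if (length(newt)) {
        u$vel[newt, ] <- u$vel[newt, ] + (u$force[newt, , drop = FALSE] / u$mass[newt]) * u$dt
        u$pos[newt, ] <- u$pos[newt, ] + u$vel[newt, , drop = FALSE] * u$dt
      }
      if (length(over)) {
        v <- u$force[over, , drop = FALSE] / u$mass[over]
        step_d <- v * u$dt
        if (is.finite(u$overdamped_cap)) {
          nrm <- sqrt(rowSums(step_d^2))
          big <- nrm > u$overdamped_cap
          if (any(big)) {
            step_d[big, ] <- step_d[big, , drop = FALSE] *
              (u$overdamped_cap / nrm[big])
          }
        }
        u$vel[over, ] <- step_d / u$dt
        u$pos[over, ] <- u$pos[over, ] + step_d
      }
      bad <- moving[!is.finite(rowSums(u$pos[moving, , drop = FALSE])) |
                    !is.finite(rowSums(u$force[moving, , drop = FALSE]))]
      if (length(bad)) {
        stop(sprintf("non-finite position/force for particle id %d at step %d (Update stage)",
                     u$id[bad[1]], u$step_count))
      }
      bc <- apply_boundary(u$pos[moving, , drop = FALSE],
                           u$vel[moving, , drop = FALSE], u)
      u$pos[moving, ] <- bc$pos
      u$vel[moving, ] <- bc$vel
    }
    cull_dissociated(u)
    integrate_species(u, pairs, u$n_substeps)
    for (ev in u$events) {
      if (u$step_count %% ev$period == 0L) {
        res <- ev$fn(u, u$time)
        if (identical(res, "stop")) u$stop_flag <- TRUE
      }
    }
    u$step_count <- u$step_count + 1L
    u$time <- u$step_count * u$dt
    if (u$stop_flag) break
  }
  invisible(u)
}

.dynamics_of <- function(u, slots) {
  if (is.null(u$.dyn_by_type) || length(u$.dyn_by_type) != length(u$type_names)) {
    u$.dyn_by_type <- vapply(u$type_names, function(nm) u$types[[nm]]$dynamics, "")
  }
  u$.dyn_by_type[u$type_id[slots]]
}

#' Run a simulation
#'
#' Steps the universe until `steps` have elapsed or an event signals stop.
#'
#' @param u a [universe]
#' @param steps number of steps
#' @return the universe, invisibly
#' @export
sim_run <- function(u, steps) {
  u$stop_flag <- FALSE
  sim_step(u, steps)
}

#' Kinetic and potential energy of the system
#'
#' Kinetic energy sums `m v^2 / 2` over live Newtonian particles; potential
#' energy is the total recorded by the most recent Force stage (implicit
#' pair terms plus bonded terms, each pair counted once).
#'
#' @param u a [universe]
#' @return named list `kinetic`, `potential`
#' @export
total_energy <- function(u) {
  live <- .live_slots(u)
  ke <- 0
  if (length(live)) {
    dyn <- .dynamics_of(u, live)
    newt <- live[dyn == "newtonian"]
    if (length(newt)) {
      ke <- sum(0.5 * u$mass[newt] * rowSums(u$vel[newt, , drop = FALSE]^2))
    }
  }
  list(kinetic = ke, potential = u$potential_energy)
}
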