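# Particle-attached chemical species. Each particle of a type carrying
# species holds a state vector; states evolve by inter-particle transport
# fluxes (evaluated over the in-cutoff pair list of the Force stage) and by
# local intra-particle reactions, integrated forward-Euler in sub-intervals
# of the time step.

#' Fickian diffusion flux between two particles
#'
#' The built-in transport flux for species exchange: the rate of change of
#' the species on particle i due to particle j is
#' `k (C_j - C_i) (1 - r/r_cutoff)^2` for `r <= r_cutoff` and 0 beyond
#' (antisymmetric under exchange of i and j, so the pair conserves mass).
#'
#' @param k flux constant (per time)
#' @param c_i,c_j species values on i and j
#' @param r separation distance(s)
#' @param r_cutoff flux cutoff distance
#' @return rate(s) of change of the species on particle i
#' @export
fickian_flux <- function(k, c_i, c_j, r, r_cutoff) {
  ifelse(r <= r_cutoff, k * (c_j - c_i) * (1 - r / r_cutoff)^2, 0)
}

#' Flux constant equivalent to a diffusion coefficient
#'
#' On a regular grid of particles with spacing `r`, particle-based Fickian
#' transport performs the same computation as the first-order central
#' finite-difference discretization of the diffusion equation. The flux
#' constant that realizes diffusivity `D` is
#' `k = D / (r^2 (1 - r/r_cutoff)^2)`, i.e. the value that makes
#' [fickian_flux()] equal `D (C_j - C_i) / r^2`.
#'
#' @param D diffusion coefficient
#' @param r grid spacing (0 < r < r_cutoff)
#' @param r_cutoff flux cutoff distance
#' @return flux constant `k`
#' @export
flux_constant_from_diffusivity <- function(D, r, r_cutoff) {
  if (!(r > 0 && r < r_cutoff)) {
    stop("the diffusivity relation requires 0 < r < r_cutoff")
  }
  D / (r^2 * (1 - r / r_cutoff)^2)
}

#' Active pump flux between two particles
#'
#' Transfers species from a source to a target particle at rate
#' `k C_source (1 - r/r_cutoff)^2` for `r <= r_cutoff` (0 beyond). The
#' amount removed from the source equals the amount added to the target;
#' states floor at zero within a sub-interval.
#'
#' @param k pump rate constant (per time)
#' @param c_source species value on the source particle
#' @param r separation distance(s)
#' @param r_cutoff flux cutoff distance
#' @return transfer rate(s) source -> target
#' @export
pump_flux <- function(k, c_source, r, r_cutoff) {
  ifelse(r <= r_cutoff, k * c_source * (1 - r / r_cutoff)^2, 0)
}

#' Declare a transport flux rule
#'
#' A flux rule applies one transport law to one species between particles
#' of a pair of types, with its own rate constant and cutoff (at most the
#' universe cutoff). Both types must declare the species. For `"pump"`
#' rules, `direction = "a_to_b"` pumps from the type-A particle of each pair
#' to the type-B particle (`"b_to_a"` reverses).
#'
#' @param u a [universe]
#' @param species species name
#' @param type_a,type_b type names or handles
#' @param kind `"fick"` or `"pump"`
#' @param k nonnegative rate constant
#' @param r_cutoff flux cutoff (defaults to the universe cutoff)
#' @param direction pump direction, `"a_to_b"` or `"b_to_a"`
#' @export
add_flux_rule <- function(u, species, type_a, type_b, kind = c("fick", "pump"),
                          k = 1, r_cutoff = NULL, direction = "a_to_b") {
  kind <- match.arg(kind)
  ta <- get_type(u, type_a); tb <- get_type(u, type_b)
  if (is.null(r_cutoff)) r_cutoff <- u$cutoff
  if (!(k >= 0)) stop("flux constant `k` must be nonnegative")
  if (!(r_cutoff > 0 && r_cutoff <= u$cutoff)) {
    stop("flux `r_cutoff` must be positive and at most the universe cutoff")
  }
  for (t in list(ta, tb)) {
    if (!(species %in% t$species_names)) {
      stop(sprintf("type '%s' does not declare species '%s'", t$name, species))
    }
  }
  if (!direction %in% c("a_to_b", "b_to_a")) stop("bad pump `direction`")
  u$flux_rules <- c(u$flux_rules, list(list(
    species = species, a = ta$type_id, b = tb$type_id,
    a_name = ta$name, b_name = tb$name,
    kind = kind, k = k, r_cutoff = r_cutoff, direction = direction)))
  invisible(u)
}

#' Attach a local reaction to a particle type
#'
#' The callback implements the intra-particle reaction term: it receives
#' the state matrix of all live particles of the type (rows = particles,
#' columns = the universe species table), the sub-interval length, the
#' universe, and the particle ids, and returns the state *increment* for the
#' sub-interval (same shape). Reactions are evaluated from the same state
#' snapshot as the transport fluxes of the sub-interval (no sequential
#' bias).
#'
#' @param u a [universe]
#' @param type type name or handle
#' @param fn `function(state, dt_sub, u, ids) -> increment matrix`
#' @param name registry name (required for JSON serialization)
#' @export
add_reaction <- function(u, type, fn, name = NULL) {
  t <- get_type(u, type)
  stopifnot(is.function(fn))
  if (!is.null(name)) register_callback(name, fn)
  u$reactions <- c(u$reactions, list(list(type = t$type_id, type_name = t$name,
                                          fn = fn, name = name)))
  invisible(u)
}

#' Integrate species transport and reactions over one time step
#'
#' Splits the step into `n_substeps` sub-intervals. In each: all pairwise
#' transport fluxes over the in-cutoff pair list and all reaction increments
#' are evaluated from the current states, then every state vector is updated
#' simultaneously (forward Euler). Negative states are clamped to zero and
#' counted in `u$clamp_warnings` (an overshoot symptom: reduce `k dt` or
#' raise `n_substeps`).
#'
#' Called automatically by [sim_step()]; exposed for direct use with a
#' custom pair list.
#'
#' @param u a [universe]
#' @param pairs pair list from the Force stage (NULL to recompute)
#' @param n_substeps number of sub-intervals (>= 1)
#' @export
integrate_species <- function(u, pairs = NULL, n_substeps = u$n_substeps) {
  if (!length(u$species)) return(invisible(u))
  if (!length(u$flux_rules) && !length(u$reactions)) return(invisible(u))
  if (is.null(pairs)) pairs <- enumerate_pairs(u)
  stopifnot(n_substeps >= 1)
  dt_sub <- u$dt / n_substeps
  np <- length(pairs$ii)
  ti <- if (np) u$type_id[pairs$ii] else integer(0)
  tj <- if (np) u$type_id[pairs$jj] else integer(0)
  for (sub in seq_len(n_substeps)) {
    dC <- matrix(0, u$cap, length(u$species))
    if (np) for (rule in u$flux_rules) {
      jcol <- match(rule$species, u$species)
      ab <- ti == rule$a & tj == rule$b
      ba <- ti == rule$b & tj == rule$a
      sel <- which((ab | ba) & pairs$r <= rule$r_cutoff)
      if (!length(sel)) next
      w2 <- (1 - pairs$r[sel] / rule$r_cutoff)^2
      si <- pairs$ii[sel]; sj <- pairs$jj[sel]
      if (rule$kind == "fick") {
        q <- rule$k * (u$state[sj, jcol] - u$state[si, jcol]) * w2
        src <- sj; tgt <- si       # q is the rate gained by i (lost by j)
      } else {
        a_first <- ab[sel]
        src <- ifelse(a_first, si, sj)
        tgt <- ifelse(a_first, sj, si)
        if (rule$direction == "b_to_a") { tmp <- src; src <- tgt; tgt <- tmp }
        q <- rule$k * u$state[src, jcol] * w2
      }
      acc <- rowsum(c(q, -q), c(tgt, src), reorder = TRUE)
      idx <- as.integer(rownames(acc))
      dC[idx, jcol] <- dC[idx, jcol] + acc[, 1]
    }
    inc <- NULL
    if (length(u$reactions)) {
      inc <- list()
      for (ridx in seq_along(u$reactions)) {
        rc <- u$reactions[[ridx]]
        slots <- .live_slots(u)
        slots <- slots[u$type_id[slots] == rc$type]
        if (!length(slots)) next
        st <- u$state[slots, , drop = FALSE]
        colnames(st) <- u$species
        d <- rc$fn(st, dt_sub, u, u$id[slots])
        if (any(!is.finite(d))) stop("reaction increment is non-finite")
        inc[[length(inc) + 1]] <- list(slots = slots, d = d)
      }
    }
    u$state <- u$state + dC * dt_sub
    if (!is.null(inc)) for (x in inc) {
      u$state[x$slots, ] <- u$state[x$slots, , drop = FALSE] + x$d
    }
    neg <- u$state < 0
    if (any(neg)) {
      u$clamp_warnings <- u$clamp_warnings + sum(neg)
      u$state[neg] <- 0
    }
  }
  invisible(u)
}
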