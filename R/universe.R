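#' Create a simulation universe
#'
#' The universe is the top-level container of a simulation: the spatial
#' domain, its boundary conditions, the global interaction cutoff, the time
#' step, and the registries of particle types, particles, clusters, bonded
#' interactions, potential/force bindings, flux rules and events. It has
#' reference semantics (an environment): engine operations mutate it in
#' place, as is usual for simulation state.
#'
#' The domain is the half-open box `[0, dims[k])` on each axis. Distances and
#' bond vectors use the minimum-image convention on periodic axes. Under
#' periodic boundaries the cutoff must not exceed half the smallest periodic
#' extent, so that the minimum image of any in-cutoff pair is unique.
#'
#' @param dims positive lengths of the domain box (length-3 numeric)
#' @param cutoff global cutoff distance for implicit (type-bound) pair
#'   interactions; per-potential cutoffs may be smaller but never larger
#' @param dt integration time step
#' @param boundary per-axis boundary condition, `"periodic"` or
#'   `"reflective"`; a single value is recycled to all three axes
#' @param seed integer seed for the universe's named RNG streams
#' @param n_substeps number of sub-intervals used when integrating species
#'   transport and reactions within one time step
#' @param confine_axis 0 for full 3D motion, or 1/2/3 to zero the force and
#'   velocity component on that axis (planar models run as 3D simulations
#'   confined to a plane)
#' @param overdamped_cap maximum displacement of an overdamped particle per
#'   step (default `Inf`); a standard cell-center-model safeguard that keeps
#'   freshly divided, deeply overlapping cells from being kicked across the
#'   domain by the clamped contact force
#' @return a `universe` object
#' @export
universe <- function(dims = c(10, 10, 10), cutoff = 1, dt = 0.01,
                     boundary = "periodic", seed = 1L, n_substeps = 1L,
                     confine_axis = 0L, overdamped_cap = Inf) {
  dims <- as.numeric(dims)
  if (length(dims) != 3 || any(!is.finite(dims)) || any(dims <= 0)) {
    stop("`dims` must be three positive finite lengths")
  }
  if (length(boundary) == 1) boundary <- rep(boundary, 3)
  if (!all(boundary %in% c("periodic", "reflective"))) {
    stop("`boundary` entries must be 'periodic' or 'reflective'")
  }
  if (!is.finite(cutoff) || cutoff <= 0) stop("`cutoff` must be positive")
  per <- boundary == "periodic"
  if (any(per) && cutoff > min(dims[per]) / 2) {
    stop("under periodic boundaries the cutoff must be <= half the smallest periodic extent")
  }
  if (!is.finite(dt) || dt <= 0) stop("`dt` must be positive")

  u <- new.env(parent = emptyenv())
  u$dims <- dims
  u$boundary <- boundary
  u$cutoff <- cutoff
  u$dt <- dt
  u$time <- 0
  u$step_count <- 0L
  u$seed <- as.integer(seed)
  u$n_substeps <- as.integer(n_substeps)
  u$confine_axis <- as.integer(confine_axis)
  u$overdamped_cap <- overdamped_cap

  # particle storage: struct-of-arrays with capacity doubling; slots are
  # never reclaimed within a run so memory order (hence summation order)
  # is reproducible
  cap <- 64L
  u$cap <- cap
  u$n_slots <- 0L
  u$id_next <- 0L
  u$id <- integer(cap)
  u$id2slot <- integer(0)       # id -> slot (1-based), NA when dead
  u$type_id <- integer(cap)
  u$alive <- logical(cap)
  u$frozen <- logical(cap)
  u$mass <- numeric(cap)
  u$radius <- numeric(cap)
  u$cluster_id <- rep(NA_integer_, cap)
  u$top_cluster <- rep(NA_integer_, cap)
  u$pos <- matrix(0, cap, 3)
  u$vel <- matrix(0, cap, 3)
  u$force <- matrix(0, cap, 3)

  u$species <- character(0)
  u$state <- matrix(0, cap, 0)

  u$types <- list()
  u$type_names <- character(0)

  u$clusters <- list()
  u$cluster_id_next <- 0L

  u$bonds <- .empty_bonded(c("i", "j"))
  u$angles <- .empty_bonded(c("i", "j", "k"))
  u$dihedrals <- .empty_bonded(c("i", "j", "k", "l"))
  u$bond_id_next <- 0L

  u$bindings <- list()     # implicit type-pair potential bindings
  u$explicit <- list()     # per-type explicit forces
  u$flux_rules <- list()
  u$reactions <- list()

  u$events <- list()
  u$event_id_next <- 0L
  u$stop_flag <- FALSE

  u$rng <- rng_init(u$seed)
  u$potential_energy <- 0
  u$clamp_warnings <- 0L
  u$grid <- NULL
  u$model <- new.env(parent = emptyenv())

  class(u) <- "universe"
  u
}

.empty_bonded <- function(endpoints) {
  b <- list(id = integer(0), pot = list(), diss = numeric(0),
            energy = numeric(0))
  for (e in endpoints) b[[e]] <- integer(0)
  b$endpoints <- endpoints
  b
}

#' @export
print.universe <- function(x, ...) {
  cat("<universe>", sprintf("%g x %g x %g", x$dims[1], x$dims[2], x$dims[3]),
      paste0("[", paste(substr(x$boundary, 1, 1), collapse = ""), "]"),
      sprintf("cutoff=%g dt=%g", x$cutoff, x$dt), "\n")
  cat("  time", format(x$time), "step", x$step_count,
      "| particles:", particle_count(x),
      "types:", length(x$type_names),
      "bonds:", sum(is.finite(x$bonds$id)) , "\n")
  invisible(x)
}

# ---- particle types --------------------------------------------------------

#' Define a particle type
#'
#' A particle type is a categorical descriptor that particles instantiate and
#' inherit from: its mass (Newtonian dynamics) or drag coefficient
#' (overdamped dynamics), a radius used for placement and rendering, the
#' dynamics law, and the chemical species its particles carry.
#'
#' @param name unique type name
#' @param mass positive real; interpreted as inertial mass under
#'   `"newtonian"` dynamics and as the drag coefficient under `"overdamped"`
#' @param radius nonnegative radius (placement/rendering only; it does not
#'   enter force calculations)
#' @param dynamics `"newtonian"` or `"overdamped"`
#' @param species character vector of species names carried by particles of
#'   this type (no duplicates)
#' @param frozen logical; particles of this type are created frozen (they
#'   accumulate forces but never move)
#' @return a `particle_type` descriptor
#' @export
particle_type <- function(name, mass = 1, radius = 0.5,
                          dynamics = c("overdamped", "newtonian"),
                          species = character(0), frozen = FALSE) {
  dynamics <- match.arg(dynamics)
  if (!is.character(name) || length(name) != 1 || !nzchar(name)) {
    stop("type `name` must be a non-empty string")
  }
  if (!is.finite(mass) || mass <= 0) stop("type `mass` must be positive")
  if (!is.finite(radius) || radius < 0) stop("type `radius` must be nonnegative")
  if (anyDuplicated(species)) stop("type `species` must have no duplicates")
  structure(list(name = name, mass = mass, radius = radius,
                 dynamics = dynamics, species_names = as.character(species),
                 frozen_default = isTRUE(frozen)),
            class = "particle_type")
}

#' Register a particle type with a universe
#'
#' @param u a [universe]
#' @param spec a [particle_type] descriptor
#' @return the registered type handle, invisibly usable by name
#' @export
register_type <- function(u, spec) {
  stopifnot(inherits(u, "universe"), inherits(spec, "particle_type"))
  if (spec$name %in% u$type_names) {
    stop(sprintf("particle type '%s' is already registered", spec$name))
  }
  spec$type_id <- length(u$type_names) + 1L
  u$type_names <- c(u$type_names, spec$name)
  u$types[[spec$name]] <- spec
  # grow the global species table with any new species names
  new_sp <- setdiff(spec$species_names, u$species)
  if (length(new_sp)) {
    u$species <- c(u$species, new_sp)
    u$state <- cbind(u$state, matrix(0, u$cap, length(new_sp)))
  }
  invisible(spec)
}

#' Look up a registered type
#' @param u a [universe]
#' @param type a type name or `particle_type` handle
#' @return the registered `particle_type`
#' @export
get_type <- function(u, type) {
  name <- if (inherits(type, "particle_type")) type$name else as.character(type)
  t <- u$types[[name]]
  if (is.null(t)) stop(sprintf("unknown particle type '%s'", name))
  t
}

# ---- particle lifecycle ----------------------------------------------------

.ensure_capacity <- function(u, n_extra) {
  need <- u$n_slots + n_extra
  if (need <= u$cap) return(invisible())
  new_cap <- u$cap
  while (new_cap < need) new_cap <- new_cap * 2L
  grow_v <- function(v, fill) c(v, rep(fill, new_cap - u$cap))
  u$id <- grow_v(u$id, 0L); u$type_id <- grow_v(u$type_id, 0L)
  u$alive <- grow_v(u$alive, FALSE); u$frozen <- grow_v(u$frozen, FALSE)
  u$mass <- grow_v(u$mass, 0); u$radius <- grow_v(u$radius, 0)
  u$cluster_id <- grow_v(u$cluster_id, NA_integer_)
  u$top_cluster <- grow_v(u$top_cluster, NA_integer_)
  grow_m <- function(m) rbind(m, matrix(0, new_cap - u$cap, ncol(m)))
  u$pos <- grow_m(u$pos); u$vel <- grow_m(u$vel); u$force <- grow_m(u$force)
  u$state <- grow_m(u$state)
  u$cap <- new_cap
  invisible()
}

#' Create particles
#'
#' Creates one or more particles of a registered type. Each particle receives
#' the next monotonically increasing id (ids start at 0 and are never
#' reused), inherits mass, radius, frozen flag and species list from its
#' type (all overridable per particle afterwards), and has its position
#' wrapped or clamped according to the boundary conditions.
#'
#' @param u a [universe]
#' @param type type name or handle (must be registered)
#' @param position numeric 3-vector, or an n-by-3 matrix for bulk creation
#' @param velocity matching 3-vector / matrix; defaults to rest
#' @param frozen optional logical override of the type's frozen default
#' @return integer vector of new particle ids
#' @export
create_particle <- function(u, type, position, velocity = NULL, frozen = NULL) {
  t <- get_type(u, type)
  pos <- if (is.matrix(position)) position else matrix(position, 1, 3, byrow = TRUE)
  if (ncol(pos) != 3) stop("`position` must have three columns")
  if (any(!is.finite(pos))) stop("particle positions must be finite")
  n <- nrow(pos)
  vel <- if (is.null(velocity)) matrix(0, n, 3)
         else if (is.matrix(velocity)) velocity else matrix(velocity, n, 3, byrow = TRUE)
  if (any(!is.finite(vel))) stop("particle velocities must be finite")
  bc <- apply_boundary(pos, vel, u)
  .ensure_capacity(u, n)
  slots <- u$n_slots + seq_len(n)
  ids <- u$id_next + seq_len(n) - 1L
  u$n_slots <- u$n_slots + n
  u$id_next <- u$id_next + n
  u$id[slots] <- ids
  u$id2slot <- c(u$id2slot, slots)
  u$type_id[slots] <- t$type_id
  u$alive[slots] <- TRUE
  u$frozen[slots] <- if (is.null(frozen)) t$frozen_default else isTRUE(frozen)
  u$mass[slots] <- t$mass
  u$radius[slots] <- t$radius
  u$pos[slots, ] <- bc$pos
  u$vel[slots, ] <- bc$vel
  ids
}

#' Destroy a particle
#'
#' Removes the particle from the universe, from its cluster (if any), and
#' destroys every bond, angle and dihedral that references it. Its id is
#' never reused.
#'
#' @param u a [universe]
#' @param ids particle id(s)
#' @export
destroy_particle <- function(u, ids) {
  for (id in ids) {
    s <- .slot_of(u, id)
    u$alive[s] <- FALSE
    u$id2slot[id + 1L] <- NA_integer_
    cid <- u$cluster_id[s]
    if (!is.na(cid)) {
      cl <- u$clusters[[as.character(cid)]]
      cl$members <- setdiff(cl$members, id)
      u$clusters[[as.character(cid)]] <- cl
      u$cluster_id[s] <- NA_integer_
      u$top_cluster[s] <- NA_integer_
    }
  }
  for (tab in c("bonds", "angles", "dihedrals")) {
    b <- u[[tab]]
    if (!length(b$id)) next
    hit <- rep(FALSE, length(b$id))
    for (e in b$endpoints) hit <- hit | (b[[e]] %in% ids)
    if (any(hit)) u[[tab]] <- .drop_bonded(b, which(hit))
  }
  invisible(u)
}

.drop_bonded <- function(b, idx) {
  keep <- setdiff(seq_along(b$id), idx)
  b$id <- b$id[keep]; b$pot <- b$pot[keep]
  b$diss <- b$diss[keep]; b$energy <- b$energy[keep]
  for (e in b$endpoints) b[[e]] <- b[[e]][keep]
  b
}

.slot_of <- function(u, id) {
  if (any(id < 0) || any(id >= u$id_next)) stop(sprintf("unknown particle id %s", id[1]))
  s <- u$id2slot[id + 1L]
  if (any(is.na(s))) stop(sprintf("particle id %s is not alive", id[which(is.na(s))[1]]))
  s
}

#' Number of live particles
#' @param u a [universe]
#' @param type optional type name to count only one type
#' @return integer count
#' @export
particle_count <- function(u, type = NULL) {
  a <- u$alive[seq_len(u$n_slots)]
  if (!is.null(type)) {
    t <- get_type(u, type)
    a <- a & u$type_id[seq_len(u$n_slots)] == t$type_id
  }
  sum(a)
}

#' Ids of live particles
#' @param u a [universe]
#' @param type optional type filter
#' @return integer vector of ids (ascending)
#' @export
particle_ids <- function(u, type = NULL) {
  s <- .live_slots(u, type)
  sort(u$id[s])
}

.live_slots <- function(u, type = NULL) {
  s <- which(u$alive[seq_len(u$n_slots)])
  if (!is.null(type)) {
    t <- get_type(u, type)
    s <- s[u$type_id[s] == t$type_id]
  }
  s
}

#' Positions / velocities / states of live particles
#'
#' Accessors returning matrices with one row per live particle, row names
#' giving particle ids. `states()` columns are the universe's species table.
#'
#' @param u a [universe]
#' @param type optional type filter
#' @return numeric matrix
#' @export
positions <- function(u, type = NULL) {
  s <- .live_slots(u, type)
  m <- u$pos[s, , drop = FALSE]
  rownames(m) <- u$id[s]
  m
}

#' @rdname positions
#' @export
velocities <- function(u, type = NULL) {
  s <- .live_slots(u, type)
  m <- u$vel[s, , drop = FALSE]
  rownames(m) <- u$id[s]
  m
}

#' @rdname positions
#' @export
states <- function(u, type = NULL) {
  s <- .live_slots(u, type)
  m <- u$state[s, , drop = FALSE]
  rownames(m) <- u$id[s]
  colnames(m) <- u$species
  m
}

#' Read or modify a single particle
#' @param u a [universe]
#' @param id particle id
#' @return `get_particle()`: a list with the particle's fields
#' @export
get_particle <- function(u, id) {
  s <- .slot_of(u, id)
  st <- u$state[s, ]
  names(st) <- u$species
  list(id = u$id[s], type = u$type_names[u$type_id[s]],
       position = u$pos[s, ], velocity = u$vel[s, ], force = u$force[s, ],
       mass = u$mass[s], radius = u$radius[s], frozen = u$frozen[s],
       cluster_id = u$cluster_id[s], state = st)
}

#' @rdname get_particle
#' @param position,velocity,mass,frozen fields to overwrite (NULL = keep)
#' @export
set_particle <- function(u, id, position = NULL, velocity = NULL,
                         mass = NULL, frozen = NULL) {
  s <- .slot_of(u, id)
  if (!is.null(position)) {
    bc <- apply_boundary(matrix(position, 1, 3), u$vel[s, , drop = FALSE], u)
    u$pos[s, ] <- bc$pos
    u$vel[s, ] <- bc$vel
  }
  if (!is.null(velocity)) u$vel[s, ] <- velocity
  if (!is.null(mass)) {
    if (!is.finite(mass) || mass <= 0) stop("`mass` must be positive")
    u$mass[s] <- mass
  }
  if (!is.null(frozen)) u$frozen[s] <- isTRUE(frozen)
  invisible(u)
}

#' Read or set a species value on particles
#' @param u a [universe]
#' @param ids particle ids
#' @param species species name
#' @param value replacement values (recycled)
#' @export
set_species <- function(u, ids, species, value) {
  j <- match(species, u$species)
  if (is.na(j)) stop(sprintf("unknown species '%s'", species))
  u$state[.slot_of(u, ids), j] <- value
  invisible(u)
}

#' @rdname set_species
#' @export
get_species <- function(u, ids, species) {
  j <- match(species, u$species)
  if (is.na(j)) stop(sprintf("unknown species '%s'", species))
  u$state[.slot_of(u, ids), j]
}

# ---- boundaries and distances ---------------------------------------------

#' Apply boundary conditions to positions and velocities
#'
#' Periodic axes wrap coordinates into `[0, L)`; reflective axes mirror the
#' coordinate about the violated wall and negate the normal velocity
#' component. Already-in-range coordinates are untouched (idempotent).
#'
#' @param pos n-by-3 position matrix (or 3-vector)
#' @param vel matching velocity matrix (or 3-vector)
#' @param u a [universe]
#' @return list with wrapped `pos` and adjusted `vel`
#' @export
apply_boundary <- function(pos, vel, u) {
  p <- if (is.matrix(pos)) pos else matrix(pos, 1, 3, byrow = TRUE)
  v <- if (is.matrix(vel)) vel else matrix(vel, 1, 3, byrow = TRUE)
  for (ax in 1:3) {
    L <- u$dims[ax]
    if (u$boundary[ax] == "periodic") {
      p[, ax] <- p[, ax] %% L
    } else {
      # fold onto the 2L-periodic triangle wave; images from the upper half
      # of the period correspond to an odd number of wall bounces, which
      # negate the normal velocity component
      x <- p[, ax] %% (2 * L)
      odd <- x > L
      x[odd] <- 2 * L - x[odd]
      v[odd, ax] <- -v[odd, ax]
      p[, ax] <- x
    }
  }
  list(pos = p, vel = v)
}

#' Minimum-image displacement
#'
#' Displacement `to - from`, wrapped on periodic axes so each component has
#' the smallest magnitude among periodic images.
#'
#' @param from,to n-by-3 matrices or 3-vectors
#' @param u a [universe]
#' @return displacement matrix (or vector)
#' @export
min_image <- function(from, to, u) {
  d <- to - from
  vec <- !is.matrix(d)
  if (vec) d <- matrix(d, 1, 3, byrow = TRUE)
  for (ax in 1:3) {
    if (u$boundary[ax] == "periodic") {
      L <- u$dims[ax]
      d[, ax] <- d[, ax] - L * round(d[, ax] / L)
    }
  }
  if (vec) d[1, ] else d
}

#' Particles within a distance of a particle
#'
#' Returns ids of live particles whose minimum-image center distance from
#' the given particle is at most `distance`, excluding the particle itself.
#'
#' @param u a [universe]
#' @param id particle id
#' @param distance query radius
#' @param type optional type filter on the returned particles
#' @return integer vector of ids (possibly empty)
#' @export
neighbor_query <- function(u, id, distance, type = NULL) {
  s0 <- .slot_of(u, id)
  s <- .live_slots(u, type)
  s <- s[s != s0]
  if (!length(s)) return(integer(0))
  d <- min_image(matrix(u$pos[s0, ], length(s), 3, byrow = TRUE),
                 u$pos[s, , drop = FALSE], u)
  r2 <- rowSums(d * d)
  sort(u$id[s[r2 <= distance^2]])
}

# ---- clusters --------------------------------------------------------------

#' Create a cluster
#'
#' A cluster is a special particle-like aggregate whose elements are
#' particles or other clusters. Clusters scope *bound* (same top-level
#' cluster) versus *unbound* (everything else) implicit interactions.
#' Membership is acyclic; a particle belongs to at most one cluster.
#'
#' @param u a [universe]
#' @param particle_ids particle ids to enrol
#' @param cluster_ids child cluster ids to enrol
#' @return the new cluster id
#' @export
new_cluster <- function(u, particle_ids = integer(0), cluster_ids = integer(0)) {
  cid <- u$cluster_id_next
  u$cluster_id_next <- cid + 1L
  u$clusters[[as.character(cid)]] <-
    list(id = cid, members = integer(0), children = integer(0), parent = NA_integer_)
  if (length(particle_ids)) cluster_add(u, cid, particle_ids = particle_ids)
  if (length(cluster_ids)) cluster_add(u, cid, cluster_ids = cluster_ids)
  cid
}

#' @rdname new_cluster
#' @param cid cluster id to add members to
#' @export
cluster_add <- function(u, cid, particle_ids = integer(0), cluster_ids = integer(0)) {
  key <- as.character(cid)
  cl <- u$clusters[[key]]
  if (is.null(cl)) stop(sprintf("unknown cluster %s", cid))
  for (id in particle_ids) {
    s <- .slot_of(u, id)
    if (!is.na(u$cluster_id[s])) stop(sprintf("particle %d already belongs to a cluster", id))
    u$cluster_id[s] <- cid
    cl$members <- c(cl$members, id)
  }
  for (child in cluster_ids) {
    ch <- u$clusters[[as.character(child)]]
    if (is.null(ch)) stop(sprintf("unknown cluster %s", child))
    if (!is.na(ch$parent)) stop(sprintf("cluster %d already has a parent", child))
    # acyclicity: the child must not be an ancestor of cid
    p <- cid
    while (!is.na(p)) {
      if (p == child) stop("cluster membership must be acyclic")
      p <- u$clusters[[as.character(p)]]$parent
    }
    ch$parent <- cid
    u$clusters[[as.character(child)]] <- ch
    cl$children <- c(cl$children, child)
  }
  u$clusters[[key]] <- cl
  .refresh_top_clusters(u)
  invisible(cid)
}

#' Top-level cluster of a particle
#' @param u a [universe]
#' @param id particle id
#' @return cluster id at the top of the nesting, or `NA` if unclustered
#' @export
top_cluster <- function(u, id) u$top_cluster[.slot_of(u, id)]

.refresh_top_clusters <- function(u) {
  # resolve each cluster to its top-level ancestor once, then map particles
  top_of <- new.env(parent = emptyenv())
  resolve <- function(cid) {
    key <- as.character(cid)
    if (!is.null(top_of[[key]])) return(top_of[[key]])
    p <- u$clusters[[key]]$parent
    top <- if (is.na(p)) cid else resolve(p)
    top_of[[key]] <- top
    top
  }
  n <- u$n_slots
  tc <- rep(NA_integer_, u$cap)
  cid <- u$cluster_id[seq_len(n)]
  has <- which(!is.na(cid))
  for (s in has) tc[s] <- resolve(cid[s])
  u$top_cluster <- tc
  invisible(u)
}
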