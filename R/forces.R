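# Explicit forces act per particle (not derived from a pair potential) and
# are bound to particle types, e.g. gravity, friction, or thermal noise.

#' Explicit per-particle forces
#'
#' \describe{
#'   \item{`force_constant(f0)`}{constant force vector `f0` on every particle
#'     of the bound type (e.g. gravity).}
#'   \item{`force_friction(gamma)`}{`-gamma * v`, a drag on Newtonian
#'     particles.}
#'   \item{`force_langevin(gamma, kbt)`}{Gaussian thermal kicks
#'     `sqrt(2 gamma kbt / dt) * xi` per axis, `xi ~ N(0,1)`; paired with
#'     `force_friction(gamma)` this thermostats Newtonian particles at
#'     temperature `kbt`.}
#'   \item{`force_custom(fn, name)`}{`fn(u, ids)` returning an n-by-3 force
#'     matrix for the given particle ids; `name` allows serialization.}
#' }
#'
#' @param f0 force 3-vector
#' @param gamma friction coefficient (>= 0)
#' @param kbt thermal energy (> 0)
#' @param fn callback `function(u, ids) -> matrix`
#' @param name registry name for serialization
#' @return an `explicit_force`
#' @export
force_constant <- function(f0) {
  stopifnot(length(f0) == 3, all(is.finite(f0)))
  structure(list(kind = "constant", f0 = as.numeric(f0)), class = "explicit_force")
}

#' @rdname force_constant
#' @export
force_friction <- function(gamma) {
  stopifnot(is.finite(gamma), gamma >= 0)
  structure(list(kind = "friction", gamma = gamma), class = "explicit_force")
}

#' @rdname force_constant
#' @export
force_langevin <- function(gamma, kbt) {
  stopifnot(is.finite(gamma), gamma >= 0, is.finite(kbt), kbt > 0)
  structure(list(kind = "langevin", gamma = gamma, kbt = kbt),
            class = "explicit_force")
}

#' @rdname force_constant
#' @export
force_custom <- function(fn, name = NULL) {
  stopifnot(is.function(fn))
  structure(list(kind = "custom", fn = fn, name = name), class = "explicit_force")
}

#' Bind a potential to a pair of particle types
#'
#' Bound potentials generate *implicit* interactions: every in-cutoff pair
#' of particles whose types match the binding (in either order) interacts
#' through the potential. The `mode` scopes the interaction by cluster
#' membership: `"bound"` applies only between particles sharing the same
#' top-level cluster (e.g. intracellular), `"unbound"` applies to all other
#' pairs (different clusters, or unclustered particles; e.g. intercellular),
#' `"all"` ignores clusters. The effective cutoff of each potential term is
#' `min(r_max, universe cutoff)`.
#'
#' @param u a [universe]
#' @param type_a,type_b type names or handles (may be equal)
#' @param pot a [potential]
#' @param mode `"all"`, `"bound"` or `"unbound"`
#' @export
bind_potential <- function(u, type_a, type_b, pot, mode = c("all", "bound", "unbound")) {
  mode <- match.arg(mode)
  ta <- get_type(u, type_a); tb <- get_type(u, type_b)
  stopifnot(inherits(pot, "potential"))
  u$bindings <- c(u$bindings, list(list(
    a = ta$type_id, b = tb$type_id, a_name = ta$name, b_name = tb$name,
    mode = mode, pot = pot, leaves = flatten_potential(pot))))
  invisible(u)
}

#' Bind an explicit force to a particle type
#'
#' @param u a [universe]
#' @param type type name or handle
#' @param force an `explicit_force`
#' @export
bind_force <- function(u, type, force) {
  t <- get_type(u, type)
  stopifnot(inherits(force, "explicit_force"))
  u$explicit <- c(u$explicit, list(list(type = t$type_id, type_name = t$name,
                                        force = force)))
  invisible(u)
}

force_to_list <- function(f) {
  if (f$kind == "custom") {
    if (is.null(f$name)) stop("custom explicit forces must carry a registry `name` to be serialized")
    list(kind = "custom", name = f$name)
  } else unclass(f)
}

force_from_list <- function(x) {
  switch(x$kind,
    constant = force_constant(unlist(x$f0)),
    friction = force_friction(x$gamma),
    langevin = force_langevin(x$gamma, x$kbt),
    custom = force_custom(get_callback(x$name), name = x$name),
    stop(sprintf("unknown explicit force kind '%s'", x$kind)))
}
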