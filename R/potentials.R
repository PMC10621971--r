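# Pairwise potentials are process objects: each carries vectorized energy
# and derivative evaluators over a scalar abscissa (a separation distance
# for pair/bond potentials, an angle for angle/dihedral potentials), an
# evaluation range [r_min, r_max), and -- for "sum" nodes -- two children to
# which evaluation requests are forwarded and whose results are added.

new_potential <- function(kind, params, r_min, r_max, u_fn, du_fn,
                          children = NULL, name = NULL) {
  # r_min may be negative for potentials over signed abscissae
  # (torsion angles range over (-pi, pi])
  if (!is.finite(r_min)) stop("`r_min` must be finite")
  if (!(r_max > r_min)) stop("`r_max` must exceed `r_min`")
  structure(list(kind = kind, params = params, r_min = r_min, r_max = r_max,
                 u_fn = u_fn, du_fn = du_fn, children = children, name = name),
            class = "potential")
}

#' @export
print.potential <- function(x, ...) {
  if (x$kind == "sum") {
    cat("<potential sum>\n")
  } else {
    ps <- paste(names(x$params), vapply(x$params, format, ""), sep = "=", collapse = ", ")
    cat(sprintf("<potential %s(%s) on [%g, %g)>\n", x$kind, ps, x$r_min, x$r_max))
  }
  invisible(x)
}

#' Built-in pair potentials
#'
#' Constructors for the built-in potential families. Conventions:
#' \describe{
#'   \item{harmonic}{`U(r) = k (r - r0)^2`}
#'   \item{lennard_jones}{`U(r) = A / r^12 - B / r^6`}
#'   \item{morse}{`U(r) = d ((1 - exp(-a (r - r0)))^2 - 1)`, minimum `-d` at `r0`}
#'   \item{coulomb}{`U(r) = q / r` with `q` the (unit-free) charge product}
#' }
#' Every potential evaluates to `(0, 0)` at or beyond `r_max` (its cutoff)
#' and clamps to its value and slope at `r_min` below `r_min`, which bounds
#' forces when runtime particle insertion creates deep overlaps.
#'
#' @param k,r0 harmonic stiffness (>0) and rest length (>=0)
#' @param A,B Lennard-Jones repulsion and attraction coefficients (>0)
#' @param d,a Morse well depth and inverse width (>0)
#' @param q Coulomb charge product
#' @param r_min,r_max evaluation range
#' @return a `potential`
#' @export
potential_harmonic <- function(k, r0 = 0, r_min = 0, r_max = Inf) {
  if (!is.finite(k) || k <= 0) stop("harmonic `k` must be positive")
  if (!is.finite(r0) || r0 < 0) stop("harmonic `r0` must be nonnegative")
  new_potential("harmonic", list(k = k, r0 = r0), r_min, r_max,
                function(r) k * (r - r0)^2,
                function(r) 2 * k * (r - r0))
}

#' @rdname potential_harmonic
#' @export
potential_lennard_jones <- function(A, B, r_min = 0.1, r_max = Inf) {
  if (!is.finite(A) || A <= 0 || !is.finite(B) || B <= 0) {
    stop("Lennard-Jones `A` and `B` must be positive")
  }
  new_potential("lennard_jones", list(A = A, B = B), r_min, r_max,
                function(r) A / r^12 - B / r^6,
                function(r) -12 * A / r^13 + 6 * B / r^7)
}

#' @rdname potential_harmonic
#' @export
potential_morse <- function(d, a, r0, r_min = 0, r_max = Inf) {
  if (!is.finite(d) || d <= 0 || !is.finite(a) || a <= 0) {
    stop("Morse `d` and `a` must be positive")
  }
  if (!is.finite(r0) || r0 < 0) stop("Morse `r0` must be nonnegative")
  new_potential("morse", list(d = d, a = a, r0 = r0), r_min, r_max,
                function(r) { e <- exp(-a * (r - r0)); d * ((1 - e)^2 - 1) },
                function(r) { e <- exp(-a * (r - r0)); 2 * d * a * e * (1 - e) })
}

#' @rdname potential_harmonic
#' @export
potential_coulomb <- function(q, r_min = 0.01, r_max = Inf) {
  if (!is.finite(q)) stop("Coulomb `q` must be finite")
  new_potential("coulomb", list(q = q), r_min, r_max,
                function(r) q / r,
                function(r) -q / r^2)
}

#' Dissipative particle dynamics (DPD) pair interaction
#'
#' The tDPD pair force is a sum of a conservative, a dissipative, and a
#' random contribution, all directed along the unit separation vector
#' (Groot-Warren forms):
#' `F_C = alpha (1 - r/rc) e`,
#' `F_D = -gamma (1 - r/rc)^2 (e . v_rel) e`,
#' `F_R = sigma (1 - r/rc) xi e / sqrt(dt)`, `xi ~ N(0,1)` drawn once per
#' pair per step (momentum conserving). As a `potential` object it exposes
#' the conservative part, whose energy is `alpha rc/2 (1 - r/rc)^2`; the
#' engine adds the dissipative and random parts when the potential is bound
#' to a type pair. Choosing `sigma^2 = 2 gamma kBT` satisfies the
#' fluctuation-dissipation relation at temperature `kBT`.
#'
#' @param alpha conservative amplitude
#' @param gamma dissipative coefficient (>= 0)
#' @param sigma noise amplitude (>= 0)
#' @param rc interaction cutoff (> 0)
#' @return a `potential` of kind `"dpd"`
#' @export
potential_dpd <- function(alpha, gamma = 0, sigma = 0, rc = 1) {
  if (!is.finite(rc) || rc <= 0) stop("DPD `rc` must be positive")
  if (gamma < 0 || sigma < 0) stop("DPD `gamma` and `sigma` must be nonnegative")
  new_potential("dpd", list(alpha = alpha, gamma = gamma, sigma = sigma, rc = rc),
                0, rc,
                function(r) alpha * rc / 2 * (1 - r / rc)^2,
                function(r) -alpha * (1 - r / rc))
}

#' Custom user potential
#'
#' Wraps a user energy function of the abscissa into a `potential`. The
#' derivative is obtained by central differences with step
#' `h = 1e-6 (r_max - r_min)`. The function is sampled over the range at
#' construction; non-finite values raise an error. A `name` is required if
#' the potential is to survive JSON serialization (it is serialized by name
#' and resolved from the callback registry on import).
#'
#' @param fn vectorized function `r -> energy`
#' @param r_min,r_max finite evaluation range
#' @param name optional registry name for serialization
#' @return a `potential` of kind `"custom"`
#' @export
potential_custom <- function(fn, r_min, r_max, name = NULL) {
  if (!is.finite(r_max)) stop("custom potentials need a finite `r_max`")
  h <- 1e-6 * (r_max - r_min)
  probe <- seq(r_min + h, r_max - h, length.out = 64)
  if (any(!is.finite(fn(probe)))) {
    stop("custom potential function returns non-finite values in range")
  }
  new_potential("custom", list(), r_min, r_max,
                fn,
                function(r) (fn(r + h) - fn(r - h)) / (2 * h),
                name = name)
}

#' Sum of two potentials
#'
#' Produces a process object that forwards evaluation requests to both
#' children and returns the sum of their results. Each child applies its own
#' range (cutoff and clamp), so heterogeneous cutoffs compose correctly.
#' Nesting is allowed to arbitrary depth; `a + b` is an equivalent spelling.
#'
#' @param a,b potentials
#' @return a `potential` of kind `"sum"`
#' @export
potential_sum <- function(a, b) {
  stopifnot(inherits(a, "potential"), inherits(b, "potential"))
  new_potential("sum", list(), 0, max(a$r_max, b$r_max),
                NULL, NULL, children = list(a, b))
}

#' @export
`+.potential` <- function(e1, e2) potential_sum(e1, e2)

#' Evaluate a potential at separations
#'
#' Returns the energy `U(r)` and scalar derivative `dU/dr` at each
#' separation. The engine converts the scalar derivative into the vector
#' force on particle i as `-(dU/dr) (r_i - r_j)/r` (and the opposite on j).
#' At or beyond `r_max` the result is exactly `(0, 0)`; below `r_min` the
#' potential evaluates at `r_min` (energy and slope clamped).
#'
#' @param pot a `potential`
#' @param r vector of separation magnitudes (> 0)
#' @return list with numeric vectors `energy` and `dudr`
#' @export
evaluate_pair <- function(pot, r) {
  if (any(r <= 0)) stop("pair separation must be positive (coincident particles)")
  eval_potential(pot, r)
}

# core evaluator without the r > 0 requirement (angles may legitimately be 0)
eval_potential <- function(pot, x) {
  if (pot$kind == "sum") {
    ea <- eval_potential(pot$children[[1]], x)
    eb <- eval_potential(pot$children[[2]], x)
    return(list(energy = ea$energy + eb$energy, dudr = ea$dudr + eb$dudr))
  }
  energy <- numeric(length(x))
  dudr <- numeric(length(x))
  live <- x < pot$r_max
  if (any(live)) {
    xc <- pmax(x[live], pot$r_min)
    energy[live] <- pot$u_fn(xc)
    dudr[live] <- pot$du_fn(xc)
  }
  list(energy = energy, dudr = dudr)
}

# flatten a (possibly nested) sum into its leaf potentials; the engine
# evaluates leaves so that special kinds (dpd) keep their semantics inside sums
flatten_potential <- function(pot) {
  if (pot$kind == "sum") {
    c(flatten_potential(pot$children[[1]]), flatten_potential(pot$children[[2]]))
  } else list(pot)
}

#' DPD pair force on particle i
#'
#' Standalone evaluation of the full tDPD pair force (conservative +
#' dissipative + random) for one pair. The random term draws one standard
#' normal from the current RNG state and scales it by `1/sqrt(dt)`.
#'
#' @param pot a `potential` of kind `"dpd"` (see [potential_dpd()])
#' @param r_vec separation vector `r_i - r_j`
#' @param v_rel relative velocity `v_i - v_j`
#' @param dt time step (scales the random force)
#' @return force 3-vector acting on particle i
#' @export
dpd_pair_force <- function(pot, r_vec, v_rel, dt) {
  stopifnot(pot$kind == "dpd")
  p <- pot$params
  r <- sqrt(sum(r_vec^2))
  if (r == 0) stop("pair separation must be positive (coincident particles)")
  if (r >= p$rc) return(c(0, 0, 0))
  e <- r_vec / r
  w <- 1 - r / p$rc
  fc <- p$alpha * w
  fd <- -p$gamma * w^2 * sum(e * v_rel)
  fr <- p$sigma * w * stats::rnorm(1) / sqrt(dt)
  (fc + fd + fr) * e
}

# serialize / deserialize potentials (custom kinds by registry name)
pot_to_list <- function(pot) {
  if (pot$kind == "sum") {
    list(kind = "sum", children = lapply(pot$children, pot_to_list))
  } else if (pot$kind == "custom") {
    if (is.null(pot$name)) {
      stop("custom potentials must carry a registry `name` to be serialized")
    }
    list(kind = "custom", name = pot$name,
         r_min = pot$r_min, r_max = pot$r_max)
  } else {
    list(kind = pot$kind, params = pot$params,
         r_min = pot$r_min, r_max = pot$r_max)
  }
}

pot_from_list <- function(x) {
  # unbounded ranges serialize as the string "Inf" (or null); restore them
  x$r_min <- if (is.null(x$r_min)) 0 else as.numeric(x$r_min)
  x$r_max <- if (is.null(x$r_max)) Inf else as.numeric(x$r_max)
  switch(x$kind,
    sum = potential_sum(pot_from_list(x$children[[1]]), pot_from_list(x$children[[2]])),
    custom = {
      fn <- get_callback(x$name)
      potential_custom(fn, x$r_min, x$r_max, name = x$name)
    },
    harmonic = potential_harmonic(x$params$k, x$params$r0, x$r_min, x$r_max),
    lennard_jones = potential_lennard_jones(x$params$A, x$params$B, x$r_min, x$r_max),
    morse = potential_morse(x$params$d, x$params$a, x$params$r0, x$r_min, x$r_max),
    coulomb = potential_coulomb(x$params$q, x$r_min, x$r_max),
    dpd = potential_dpd(x$params$alpha, x$params$gamma, x$params$sigma, x$params$rc),
    stop(sprintf("unknown potential kind '%s'", x$kind))
  )
}
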