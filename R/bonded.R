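# Bonded interactions act between explicitly enumerated particles, at any
# separation (they ignore the global implicit cutoff). Displacements use the
# minimum-image convention on periodic axes so bonded structures (e.g. a
# periodic membrane sheet) work across the wrap.

#' Create bonded interactions
#'
#' A Bond applies a potential of the inter-particle distance to two
#' particles; an Angle applies a potential of the angle at the middle
#' particle `j` between arms `j->i` and `j->k`; a Dihedral applies a
#' potential of the torsion angle between the plane of `(i, j, k)` and the
#' plane of `(j, k, l)` (IUPAC sign convention: 0 at cis, positive clockwise
#' looking from `j` to `k`). Angle and dihedral potentials take the angle in
#' radians as their abscissa and reuse the ordinary [potential] evaluation
#' contract; since torsion angles are signed, a dihedral potential should
#' cover the full range, e.g. `potential_harmonic(k, phi0, r_min = -pi)`.
#'
#' If `dissociation_energy` is set, the item is automatically destroyed at
#' the end of any step in which its potential energy exceeds that threshold.
#'
#' @param u a [universe]
#' @param i,j,k,l particle ids (all distinct, all alive)
#' @param pot a [potential]
#' @param dissociation_energy optional energy threshold
#' @return the new bonded-item id
#' @export
add_bond <- function(u, i, j, pot, dissociation_energy = NA_real_) {
  if (i == j) stop("a bond needs two distinct particles")
  .slot_of(u, c(i, j))
  .add_bonded(u, "bonds", list(i = i, j = j), pot, dissociation_energy)
}

#' @rdname add_bond
#' @export
add_angle <- function(u, i, j, k, pot, dissociation_energy = NA_real_) {
  if (anyDuplicated(c(i, j, k))) stop("an angle needs three distinct particles")
  .slot_of(u, c(i, j, k))
  .add_bonded(u, "angles", list(i = i, j = j, k = k), pot, dissociation_energy)
}

#' @rdname add_bond
#' @export
add_dihedral <- function(u, i, j, k, l, pot, dissociation_energy = NA_real_) {
  if (anyDuplicated(c(i, j, k, l))) stop("a dihedral needs four distinct particles")
  .slot_of(u, c(i, j, k, l))
  .add_bonded(u, "dihedrals", list(i = i, j = j, k = k, l = l), pot,
              dissociation_energy)
}

.add_bonded <- function(u, tab, ends, pot, diss) {
  stopifnot(inherits(pot, "potential"))
  b <- u[[tab]]
  id <- u$bond_id_next
  u$bond_id_next <- id + 1L
  b$id <- c(b$id, id)
  b$pot <- c(b$pot, list(pot))
  b$diss <- c(b$diss, diss)
  b$energy <- c(b$energy, 0)
  for (e in names(ends)) b[[e]] <- c(b[[e]], as.integer(ends[[e]]))
  u[[tab]] <- b
  id
}

#' Number of live bonds / angles / dihedrals
#' @param u a [universe]
#' @return integer count
#' @export
bond_count <- function(u) length(u$bonds$id)

# ---- pure evaluators (positions in, energy and per-particle forces out) ----

#' Energy and forces of a single bond
#'
#' @param pot a [potential] over the inter-particle distance
#' @param pos_i,pos_j endpoint positions (3-vectors)
#' @param u a [universe] (supplies boundary conditions for minimum image)
#' @return list with `energy`, `r`, and forces `f_i`, `f_j` (equal and
#'   opposite along the separation)
#' @export
bond_energy_forces <- function(pot, pos_i, pos_j, u) {
  d <- min_image(pos_i, pos_j, u)          # vector i -> j
  r <- sqrt(sum(d * d))
  if (r == 0) stop("bond endpoints are coincident")
  ev <- evaluate_pair(pot, r)
  f_i <- (ev$dudr / r) * d                 # -dU/dr along (r_i - r_j)/r
  list(energy = ev$energy, r = r, f_i = f_i, f_j = -f_i)
}

#' Energy and forces of a single angle
#'
#' The angle at pivot `j` is computed as `atan2(|u x v|, u . v)` with
#' `u = r_i - r_j`, `v = r_k - r_j`, which is stable near 0 and pi. Forces
#' are the analytic gradient; configurations with `sin(theta) < 1e-8`
#' (collinear arms) contribute zero force for the step, keeping forces
#' bounded.
#'
#' @param pot a [potential] over the angle (radians)
#' @param pos_i,pos_j,pos_k positions; `j` is the pivot
#' @param u a [universe]
#' @return list with `energy`, `theta`, and forces `f_i`, `f_j`, `f_k`
#'   (summing to zero)
#' @export
angle_energy_forces <- function(pot, pos_i, pos_j, pos_k, u) {
  uu <- min_image(pos_j, pos_i, u)
  vv <- min_image(pos_j, pos_k, u)
  lu <- sqrt(sum(uu^2)); lv <- sqrt(sum(vv^2))
  if (lu == 0 || lv == 0) stop("angle arm has zero length")
  cr <- .cross(uu, vv)
  sin_t <- sqrt(sum(cr^2)) / (lu * lv)
  cos_t <- sum(uu * vv) / (lu * lv)
  theta <- atan2(sqrt(sum(cr^2)), sum(uu * vv))
  ev <- eval_potential(pot, theta)
  if (sin_t < 1e-8) {
    z <- c(0, 0, 0)
    return(list(energy = ev$energy, theta = theta, f_i = z, f_j = z, f_k = z))
  }
  uh <- uu / lu; vh <- vv / lv
  dth_di <- (uh * cos_t - vh) / (lu * sin_t)
  dth_dk <- (vh * cos_t - uh) / (lv * sin_t)
  f_i <- -ev$dudr * dth_di
  f_k <- -ev$dudr * dth_dk
  list(energy = ev$energy, theta = theta, f_i = f_i, f_j = -(f_i + f_k), f_k = f_k)
}

#' Energy and forces of a single dihedral
#'
#' Torsion angle between the plane of `(i, j, k)` and the plane of
#' `(j, k, l)`, signed by the IUPAC convention (0 at cis, range (-pi, pi]).
#' Forces are the analytic gradient; both planes must be well defined
#' (non-collinear triples).
#'
#' @param pot a [potential] over the torsion angle (radians)
#' @param pos_i,pos_j,pos_k,pos_l positions
#' @param u a [universe]
#' @return list with `energy`, `phi`, and forces `f_i`..`f_l` (summing to
#'   zero, zero net torque)
#' @export
dihedral_energy_forces <- function(pot, pos_i, pos_j, pos_k, pos_l, u) {
  b1 <- min_image(pos_i, pos_j, u)
  b2 <- min_image(pos_j, pos_k, u)
  b3 <- min_image(pos_k, pos_l, u)
  n1 <- .cross(b1, b2)
  n2 <- .cross(b2, b3)
  l1 <- sum(n1^2); l2 <- sum(n2^2); lb2 <- sqrt(sum(b2^2))
  if (l1 < 1e-16 || l2 < 1e-16 || lb2 == 0) {
    stop("dihedral plane is degenerate (collinear triple)")
  }
  # atan2 form: positive phi = clockwise rotation of the far plane looking j->k
  phi <- atan2(sum(.cross(n1, n2) * b2) / lb2, sum(n1 * n2))
  ev <- eval_potential(pot, phi)
  dphi_di <- -(lb2 / l1) * n1
  dphi_dl <- (lb2 / l2) * n2
  c12 <- sum(b1 * b2) / lb2^2
  c32 <- sum(b3 * b2) / lb2^2
  dphi_dj <- c32 * dphi_dl - (1 + c12) * dphi_di
  dphi_dk <- c12 * dphi_di - (1 + c32) * dphi_dl
  list(energy = ev$energy, phi = phi,
       f_i = -ev$dudr * dphi_di, f_j = -ev$dudr * dphi_dj,
       f_k = -ev$dudr * dphi_dk, f_l = -ev$dudr * dphi_dl)
}

.cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# accumulate all bonded forces into the universe force accumulators,
# record per-item energies (for dissociation), return total bonded energy
accumulate_bonded <- function(u) {
  total <- 0
  b <- u$bonds
  if (length(b$id)) {
    si <- .slot_of(u, b$i); sj <- .slot_of(u, b$j)
    for (n in seq_along(b$id)) {
      r <- bond_energy_forces(b$pot[[n]], u$pos[si[n], ], u$pos[sj[n], ], u)
      u$force[si[n], ] <- u$force[si[n], ] + r$f_i
      u$force[sj[n], ] <- u$force[sj[n], ] + r$f_j
      b$energy[n] <- r$energy
      total <- total + r$energy
    }
    u$bonds <- b
  }
  a <- u$angles
  if (length(a$id)) {
    si <- .slot_of(u, a$i); sj <- .slot_of(u, a$j); sk <- .slot_of(u, a$k)
    for (n in seq_along(a$id)) {
      r <- angle_energy_forces(a$pot[[n]], u$pos[si[n], ], u$pos[sj[n], ],
                               u$pos[sk[n], ], u)
      u$force[si[n], ] <- u$force[si[n], ] + r$f_i
      u$force[sj[n], ] <- u$force[sj[n], ] + r$f_j
      u$force[sk[n], ] <- u$force[sk[n], ] + r$f_k
      a$energy[n] <- r$energy
      total <- total + r$energy
    }
    u$angles <- a
  }
  d <- u$dihedrals
  if (length(d$id)) {
    si <- .slot_of(u, d$i); sj <- .slot_of(u, d$j)
    sk <- .slot_of(u, d$k); sl <- .slot_of(u, d$l)
    for (n in seq_along(d$id)) {
      r <- dihedral_energy_forces(d$pot[[n]], u$pos[si[n], ], u$pos[sj[n], ],
                                  u$pos[sk[n], ], u$pos[sl[n], ], u)
      u$force[si[n], ] <- u$force[si[n], ] + r$f_i
      u$force[sj[n], ] <- u$force[sj[n], ] + r$f_j
      u$force[sk[n], ] <- u$force[sk[n], ] + r$f_k
      u$force[sl[n], ] <- u$force[sl[n], ] + r$f_l
      d$energy[n] <- r$energy
      total <- total + r$energy
    }
    u$dihedrals <- d
  }
  total
}

#' Destroy bonded items whose energy exceeds their dissociation threshold
#'
#' Uses the per-item energies recorded by the most recent Force stage. Items
#' with no dissociation energy set are never destroyed. Called automatically
#' at the end of every step; exposed for direct use.
#'
#' @param u a [universe]
#' @return invisible list of destroyed item ids per table
#' @export
cull_dissociated <- function(u) {
  destroyed <- list()
  for (tab in c("bonds", "angles", "dihedrals")) {
    b <- u[[tab]]
    if (!length(b$id)) { destroyed[[tab]] <- integer(0); next }
    hit <- which(!is.na(b$diss) & b$energy > b$diss)
    destroyed[[tab]] <- b$id[hit]
    if (length(hit)) u[[tab]] <- .drop_bonded(b, hit)
  }
  invisible(destroyed)
}
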