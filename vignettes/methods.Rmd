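---
title: "Methods: the tissuesim particle formalism"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the tissuesim particle formalism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tissuesim)
```

tissuesim is a particle-based modeling and simulation engine for biological
systems from the molecular to the multicellular scale. A simulation is a
`universe`: a half-open box `[0, L)^3` with per-axis periodic or reflective
boundaries, a global interaction cutoff, a time step, and registries of
particle types, particles, clusters, bonded items, force bindings, species
flux rules and events. This vignette records the model, its numerical
choices, and the design decisions that were genuinely open.

## Dynamics

Each particle type selects one of two dynamics laws. Newtonian particles
obey `m dv/dt = f` and are integrated with the semi-implicit (velocity
first) forward Euler update `v <- v + (f/m) dt; r <- r + v dt`. Overdamped
(Langevin) particles neglect inertia: `m` is reinterpreted as a drag
coefficient and `r <- r + (f/m) dt`. Both are explicit first-order forward
updates; the semi-implicit ordering was chosen for Newtonian particles
because it is symplectic, so the energy of oscillatory motion stays bounded
instead of growing. One consequence worth recording: for a pure harmonic
two-body system the *phase* (period) error of this update is
superconvergent — observed order ~2 in `dt` — while the energy-envelope
error is first order. The acceptance suite therefore pins the envelope
order to 1.0 +/- 0.3 and requires the period error only to converge at
least at first order.

The net force on particle i is the sum of three classes: implicit pair
forces (potentials bound to a pair of particle types, applied automatically
within a cutoff), bonded forces (potentials attached to explicitly
enumerated tuples of particles), and explicit per-particle forces (constant
fields, friction, thermal noise, custom callbacks). Frozen particles
accumulate forces but skip integration — this is how fixed pivots and
static measurement grids are modeled. Planar (2D) models are 3D simulations
with the third force/velocity component zeroed (`confine_axis`).

## Potentials

Built-in families, with the conventions the package fixes (vectorized over
the abscissa):

| kind | form | parameters |
|---|---|---|
| harmonic | `k (r - r0)^2` | `k > 0`, `r0 >= 0` |
| lennard_jones | `A/r^12 - B/r^6` | `A, B > 0` |
| morse | `d ((1 - e^{-a(r-r0)})^2 - 1)` | `d, a > 0` |
| coulomb | `q / r` | unit-free charge product |
| dpd | Groot–Warren, see below | `alpha, gamma, sigma, rc` |

Every potential carries an evaluation range `[r_min, r_max)`. At or beyond
`r_max` it evaluates to exactly `(0, 0)` — pairs at exactly the cutoff do
not interact, matching the strict piecewise form of the transport kernel
below. Below `r_min` the potential evaluates *at* `r_min` (energy and slope
clamped). The clamp bounds the forces generated by deep overlaps, which
arise whenever particles are inserted at runtime (cell division places a
daughter at 0.1 diameters from its parent). The clamped region has zero
stiffness, which also bounds the explicit-Euler stability constraint: for
overdamped particles the step is stable where `dt * U'' < 2`, so the clamp
radius is chosen per model such that the maximum curvature `U''(r_min)`
satisfies that bound (e.g. 0.85 `r0` for the spheroid Morse potential at
`dt = 0.02`). As a second guard, a universe may cap the per-step
displacement of overdamped particles (`overdamped_cap`), a standard
cell-center-model safeguard.

Potentials are process objects: a `sum` node forwards an evaluation request
to its two children and returns the added results, each child applying its
own range. Sums nest to arbitrary depth, and evaluation of a nested sum
performs literally the same floating-point additions as the direct sum of
its leaves, which the suite asserts with `identical()`. Custom potentials
wrap a user energy function; their derivative is a central difference with
step `1e-6 (r_max - r_min)`.

The DPD (dissipative particle dynamics) interaction is the standard
Groot–Warren triple acting along the unit separation `e`:
conservative `alpha (1 - r/rc)`, dissipative
`-gamma (1 - r/rc)^2 (e . v_rel)`, and random
`sigma (1 - r/rc) xi / sqrt(dt)` with one `xi ~ N(0,1)` per pair per step
(so the pair force is equal and opposite and momentum is conserved
exactly). Choosing `sigma^2 = 2 gamma kBT` satisfies fluctuation–
dissipation; the suite verifies a dense fluid equilibrates to within a few
percent of the target `kBT`. The fluctuation–dissipation relation is *not*
enforced automatically — `sigma` is a free parameter unless the user ties
it to a temperature.

## Bonded interactions

Bonds (distance), angles (angle at the middle particle) and dihedrals
(torsion between two planes, IUPAC sign convention: 0 at cis, positive
clockwise looking down the central bond) reuse the ordinary potential
contract with the angle in radians as abscissa; a dihedral potential should
cover `(-pi, pi]` via `r_min = -pi`. All bonded displacement vectors are
minimum-image, so bonded sheets work across periodic wraps, and bonded
terms ignore the global cutoff entirely (a stretched bond acts at any
length). Forces are analytic gradients; the angle gradient is guarded near
collinearity (`sin theta < 1e-8` contributes zero force for that step,
trading a measure-zero configuration for bounded forces). Any bonded item
may carry a dissociation energy: at the end of every step, items whose
just-computed potential energy exceeds the threshold are destroyed. The
threshold is exposed uniformly for bonds, angles and dihedrals.

## The simulation loop

Each step runs three stages. *Prep* zeroes the force accumulators. *Force*
builds the cell decomposition — a regular grid with cells at least one
cutoff wide per axis (axes narrower than a cutoff collapse to one cell) —
enumerates in-cutoff pairs once each (self pairs within a cell, cross pairs
over deduplicated neighbor-cell pairs including periodic wraps), and
accumulates implicit, bonded and explicit forces plus transport fluxes.
*Update* integrates trajectories, applies boundary conditions (periodic
wrap into `[0, L)`; reflective fold with normal-velocity negation),
re-indexes particles into cells, culls dissociated bonded items, integrates
species, and finally dispatches events. Event order within a step is fixed
as last-after-species, so an event callback always observes a fully
consistent post-integration state; events due at the same step fire in
registration order.

The engine is single-threaded but preserves the Sort / Force-Pair /
Force-Self task decomposition as an internal contract: `sort_cell()`
exposes the projection-ordered particle lists used to prune cross-cell
pairs, and the suite checks the enumerated pair set equals a dense
minimum-image scan in both boundary modes. Determinism is a first-class
contract: identical seed and configuration give bitwise-identical
trajectories. All stochastic draws go through named, serializable RNG
streams owned by the universe (`engine` for pair noise and thermostats,
`events`, `model` for fixture generation).

## Species transport and reactions

Particles carry a state vector aligned with their type's species list. The
built-in Fickian flux between particles i and j at distance `r` changes the
species on i at rate `k (C_j - C_i) (1 - r/rc)^2` for `r <= rc`, zero
beyond; the active pump moves `k C_source (1 - r/rc)^2` from a source to a
target particle (conservative transfer; secretion and uptake are the pump
plus a constant source/sink reaction). On a regular grid with spacing `h`
and a cutoff between `h` and the diagonal, choosing
`k = D / (h^2 (1 - h/rc)^2)` makes the particle update identical to the
FTCS (forward-time, central-space) finite-difference solution of the
diffusion equation with zero-flux boundaries — the suite asserts equality
to 1e-10 over 100 steps on a 32 x 32 grid. This is the reading of the
diffusivity relation under which the kernel algebraically reduces to
`D (C_j - C_i) / h^2`; the alternative bracketing (multiplying rather than
dividing by the kernel) does not reproduce finite differences and was
rejected.

Fluxes are evaluated over the Force-stage pair list; state updates happen
in Update, split into `n_substeps` sub-intervals. In each sub-interval all
flux rates and reaction increments are computed from the same state
snapshot and applied simultaneously (no sequential bias), so halving the
sub-interval halves the forward-Euler error (verified against the matrix
exponential of a stiff linear fixture). Negative states are clamped to zero
and counted in `u$clamp_warnings` — an overshoot alarm, not a silent fix.
Reaction callbacks are vectorized (state matrix in, increment matrix out)
rather than per-particle; the scalar contract is the one-row special case,
and the vectorized form lets reactions use neighborhood context, which the
Delta-Notch model needs.

## State serialization

`to_json()` captures the complete engine state: header, RNG stream states,
type table, the full particle slot table (dead slots included, so memory
order — hence floating-point summation order — is reproduced exactly),
clusters, bonded tables, bindings, flux rules, reactions and events.
Numbers are emitted at 17 significant digits, which round-trips doubles
exactly; resuming from a checkpoint therefore continues *bitwise*
identically, including stochastic (DPD) runs, because the RNG streams
travel with the document. Callbacks serialize by registered name only —
JSON is data — so importing a document requires the same names in the
callback registry (the bundled model builders register theirs at load).
Auxiliary model-builder state (`u$model`: crypt cycle tables, sheet
layouts) is *not* part of the document; exact continuation is an
engine-level contract.

## The worked multicellular models

**Oscillator and pendulum.** Two Newtonian particles with a harmonic bond
(analytic period `pi sqrt(m/k)` for equal masses `m`), and a frozen pivot
with two bobs under a constant downward force. These anchor the integrator
tests.

**Spheroid fusion.** Cells are overdamped single particles interacting
through one Morse potential (`d = 0.1`, `a = 6`, `r0 = 1` cell diameter,
cutoff 2). A spheroid is assembled by filling a ball on a jittered lattice
(spacing 0.95 `r0`) and relaxing until the largest per-step displacement
falls below 1e-3. Two 500-cell spheroids start in slight contact
(`gap = -0.5`) so the neck exists at time zero, and fuse at `dt = 0.02` for
5000 steps. The neck diameter along an axis is the largest coordinate
difference between any two particles in a mid-plane slab (half width one
cell diameter). Because that is a range statistic over finitely many
particles, it is quantized: single particles entering or leaving the slab
move it by up to a particle spacing. The monotonicity check therefore runs
on a 10-census moving average and tolerates decreases up to 0.05 cell
diameters, roughly a twentieth of the observed growth; demanding strict
non-decrease of a discrete range statistic would be ill-posed.

**Colonic crypt.** The crypt is unfolded onto a plane: periodic horizontal
boundaries, a reflective floor, and a removal boundary (the crypt base) at
the top edge. Cells are overdamped particles with the Morse contact model;
each carries a four-phase cycle (G1 with per-cell duration drawn from
N(2, 0.5) truncated at zero; S = G2 = M = 1), advances on expiry, divides
on leaving M (daughter at 0.1 diameters in a uniform random planar
direction, inheriting the parent's clone id), and is removed on reaching
the base. Cycling happens only in the proliferative zone (lower 2/3) and —
following the additions this ABM family is normally run with — pauses
under contact inhibition (more than 6 neighbors within 1.1 diameters),
which caps the density and hence the population; cells also receive weak
stochastic motility kicks (Langevin, effective energy 0.01), without which
clonal coarsening stalls once a few clones tile the niche. Clone count is
exactly non-increasing (ids are copied, never minted after t = 0). The
default geometry is 20 x 10 cell diameters; the scaled-down test fixture
uses 6 x 6 with 200 founders, which reaches three or fewer clones by
t ~ 80 across seeds 0–9. In a wider crypt the same drift occurs but on a
quadratically longer timescale — a known property of niche-succession
dynamics, not an artifact.

**Delta-Notch.** A 12 x 12 hexagonally packed sheet of frozen cells
carries `notch` and `delta` species integrated by the classic two-variable
lateral-inhibition ODEs: `dn/dt = F(Dbar) - n`, `dd/dt = v (G(n) - d)`
with `F(x) = x^k/(a + x^k)`, `G(n) = 1/(1 + b n^h)`, defaults `a = 0.01`,
`b = 100`, `k = h = 2`, `v = 1` (a known patterning regime), and `Dbar`
the mean Delta over neighbors within 1.1 spacings — "contact" for
single-particle cells is a neighbor radius, exposed in the parameters.
From a uniform start perturbed by 5% noise the sheet reaches an
anti-correlated mosaic (neighbor Delta correlation below -0.3, about one
high-Delta cell in three on the hexagonal lattice). In the induced
variant, both rates are multiplied by a Hill gate on a `signal` species
that diffuses from a clamped source edge, so the patterning front follows
the diffusion front and the per-cell onset time increases with distance
from the source (Spearman rho > 0.5). Onset is the first census where
Delta deviates from its uniform equilibrium by more than 0.25.

**Membrane pump.** Two DPD fluid compartments separated by a bonded,
deformable membrane sheet (periodic in-plane), with one membrane-center
pump particle moving a cargo species from lower-compartment fluid through
itself into upper-compartment fluid; Fickian rules mix cargo within each
compartment. Cargo totals are conserved to accumulation roundoff and the
upper compartment's total is non-decreasing.

## What the synthetic fixtures do and do not show

Every test input is generated by the model builders from a seed — there are
no external data. The fixtures emulate the *mechanisms* (neighbor-limited
transport, contact-scoped interactions, cycle-driven division, lateral
inhibition), not any particular tissue's parameters; passing tests
demonstrate that the engine computes the stated models correctly and
reproducibly at desk scale, not that those models quantitatively describe a
given experimental system. Real multicellular data would add heterogeneous
cell sizes and mechanics, three-dimensional crypt geometry, and far larger
populations (bioprinting spheroids are ~12,500 cells against the 500 used
here), all of which change timescales but none of the conservation or
equivalence properties tested.

## Known limitations

Single-threaded execution; first-order integrators only; no long-range
electrostatics or shifted-force smoothing; no PDE field solver (fields are
particle grids); cluster rigid-body motion is not modeled (clusters scope
interactions; their elements move individually); JSON import requires
custom callbacks to be re-registered by name; model-builder auxiliary
state is outside the serialized document.
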