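# tissuesim

Particle-based, multiscale modeling and simulation of biological systems in
R — from interacting molecules to multicellular tissues.

Many biological questions are intrinsically spatial: fluids mix, chemicals
diffuse between neighboring portions of cytoplasm, cells push and pull on
each other, divide, die, and signal through contact. `tissuesim` provides
one engine for all of these, built on a single abstraction: the particle.
A particle can be an atom-scale bead, a parcel of fluid carrying a solute,
or an entire biological cell, depending on the model. It is aimed at
modelers who want agent-based, physics-grounded tissue simulations with
exact reproducibility, without leaving R.

## The formalism

Every particle instantiates a *type* that fixes its dynamics law and
parameters. Newtonian particles follow `m dv/dt = f`; overdamped
(Langevin) particles follow `v = f / m` with `m` a drag coefficient —
appropriate for cells, where inertia is negligible. The net force is

```
f_i = sum_j ( F_impl_ij + F_bond_ij ) + F_expl_i
```

- **Implicit forces** derive from potentials bound to pairs of types
  (harmonic, Lennard-Jones `A/r^12 - B/r^6`, Morse, Coulomb, and
  Groot–Warren DPD with conservative + dissipative + random components),
  applied automatically to every in-cutoff pair via a cell-list
  decomposition of space. Potentials are *process objects*: sums of
  potentials are potentials, nested to any depth.
- **Bonded forces** act on enumerated particles: bonds (distance), angles,
  and dihedrals (IUPAC torsion), each optionally destroyed the moment its
  energy exceeds a dissociation threshold.
- **Explicit forces** act per particle: constant fields, friction,
  Langevin thermostats, custom callbacks.

*Clusters* group particles into aggregates (e.g. a cell made of many
particles) and scope interactions into *bound* (same cluster:
intracellular) and *unbound* (different clusters: intercellular) modes.

Particles also carry chemical state vectors. Species move between nearby
particles by Fickian flux `k (C_j - C_i)(1 - r/rc)^2`, by active pumping,
and react locally, integrated in sub-intervals of the time step. On a
regular particle grid with `k = D / (h^2 (1 - h/rc)^2)` the transport is
*exactly* the finite-difference (FTCS) solution of the diffusion equation —
particles can therefore double as field solvers.

An event system injects model rules (division, removal, sources) into the
loop at configurable step frequencies, and the complete state — including
RNG stream states — serializes to human-readable JSON so that any run,
stochastic ones included, can be checkpointed and resumed *bitwise
identically*.

Bundled multicellular models, doubling as test fixtures: spheroid fusion
with a neck-diameter metric, a colonic-crypt agent-based model with
cell-cycle state machines and clonal tracking, Delta-Notch lateral
inhibition on a cell sheet (with optional diffusing-signal induction), and
a membrane-pump / two-compartment tDPD demonstration.

## A worked example

Two particles joined by a harmonic bond, the engine's "hello world":

```r
library(tissuesim)

u <- build_oscillator(k = 1, r0 = 1, m = 1, displacement = 0.4, dt = 0.005)
print(u)
#> <universe> 10 x 10 x 10 [rrr] cutoff=1 dt=0.005
#>   time 0 step 0 | particles: 2 types: 1 bonds: 1

sim_run(u, 2000)
en <- total_energy(u)
cat(sprintf("t = %.2f  separation = %.4f  E = %.6f (K = %.6f, U = %.6f)\n",
            u$time, diff(positions(u)[, 1]), en$kinetic + en$potential,
            en$kinetic, en$potential))
#> t = 10.00  separation = 1.1614  E = 0.160603 (K = 0.133368, U = 0.027234)

oscillator_period(k = 1, m = 1)
#> [1] 3.141593
```

The separation oscillates about the rest length 1 with period
`pi * sqrt(m/k) ≈ 3.14` time units; the total energy stays within an
O(dt) envelope of its initial value `k * displacement^2 / 2 + ...` because
the Newtonian update is symplectic. Swap in `build_crypt()`,
`build_spheroid_fusion()` or `build_delta_notch()` for the multicellular
models; each returns an ordinary universe you can step, query
(`positions()`, `states()`, `count_clones()`,
`neighbor_delta_correlation()`), checkpoint (`to_json()`), and extend.

A command-line front end is included for batch use:

```sh
Rscript inst/cli/tissuesim run --config inst/extdata/oscillator.json --steps 1000
Rscript inst/cli/tissuesim resume --state oscillator_out/checkpoint_000500.json --steps 500
```

writing XYZ/CSV trajectories, JSON checkpoints and a run log.

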