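Package: tissuesim
Title: Particle-Based Multiscale Simulation of Cells and Tissues
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale, particle-based modeling and simulation engine for
    biological systems from the molecular to the multicellular scale. Particles
    carry per-type dynamics (Newtonian or overdamped), interact through bindable
    pair potentials (harmonic, Lennard-Jones, Morse, Coulomb, dissipative
    particle dynamics), bonded interactions (bonds, angles, dihedrals with
    optional dissociation), and explicit per-particle forces. Particles can
    carry chemical species exchanged by Fickian or active-pump transport fluxes
    and transformed by local reactions, with sub-interval integration. A
    cell-list engine, an event system, JSON state serialization with exact
    restart, and reusable multicellular models (spheroid fusion, colonic-crypt
    clonal dynamics, Delta-Notch lateral inhibition with signal-gated
    induction) are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
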