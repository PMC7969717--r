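Package: hapbind
Title: Nanoparticle-Protein Binding Analysis: Conformational Coordinates,
    Elastic Network Modes and MM/PBSA Energetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-simulation analysis toolkit for charged-nanoparticle binding
    to two-domain proteins, motivated by hydroxyapatite uptake through
    clathrin-mediated endocytosis. Implements an open/locked conformational
    transition coordinate (lambda), distance-fluctuation matrices,
    RMSD-criterion trajectory clustering, anisotropic elastic-network normal
    modes, a finite-difference linearized Poisson-Boltzmann MM/PBSA
    binding-energy engine with per-residue decomposition and computational
    alanine scanning, and electrostatic surface characterization of idealized
    sphere, rod and needle charged particles. Includes seeded synthetic-data
    generators that emulate two-state references, lambda-targeted
    trajectories and patterned nanoparticles so every stage runs without
    external trajectory data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    Matrix,
    igraph,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    jsonlite,
    optparse
Config/testthat/edition: 3
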