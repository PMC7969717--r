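---
title: "Models and methods behind hapbind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hapbind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

hapbind is a post-simulation analysis toolkit for the binding of small
charged nanoparticles — hydroxyapatite-like spheres, rods and needles — to
a two-domain cargo-binding protein such as the mu2 subunit of the AP2
clathrin adaptor. It implements the quantities such a study reports: a
conformational transition coordinate between an open and a locked state,
distance-fluctuation matrices, RMSD clustering of trajectories,
elastic-network normal modes, MM/PBSA binding energies with per-residue
decomposition and alanine scanning, and electrostatic surface descriptors
of the particles. Because molecular-dynamics trajectories of the real
systems are not shipped with the package, a seeded synthetic-data module
generates stand-ins with known ground truth; every analysis stage is
validated against analytic identities or independent brute-force oracles
on those stand-ins.

## The transition coordinate lambda

Two reference structures define the coordinate: the open state `v1`
(lambda = 0) and the locked state `v2` (lambda = 1). For a sampled
structure `v`, lambda is the norm ratio

$$\lambda = \frac{\lVert v - v_1 \rVert}{\lVert v_2 - v_1 \rVert}$$

over the flattened coordinates of a selection, by default the C-alpha
atoms. Three conventions make this operational, and all three are
documented choices rather than uniquely determined by the definition:

* **Superposition.** A sampled frame carries an arbitrary rigid pose, so
  it is first least-squares superposed onto `v1` on the selection.
* **Canonical reference alignment.** The same argument applies to `v2`:
  unless the locked reference is already optimally aligned to the open
  one, superposing it would shrink its distance to `v1` below the axis
  norm and lambda at the locked reference itself would fall short of 1.
  `reference_pair()` therefore co-superposes `v2` onto `v1` once at
  construction and defines the axis between `v1` and the aligned copy.
  With that convention, lambda is exactly 0 at `v1` and exactly 1 at
  `v2`, and the whole segment between them maps linearly onto \[0, 1\]
  (the least-squares fit of any intermediate point on the axis is the
  identity, because the optimal-rotation condition is preserved under
  convex combination).
* **Selection.** C-alpha only, matching the convention used for the
  distance-fluctuation analysis; configurable through `SelectionSpec`.

### Noise bias and the projection variant

The norm ratio is non-negative, so isotropic positional noise inflates
it: with per-coordinate noise of standard deviation $\sigma$ on $M$
selected coordinates, the expected value at a true position $\lambda_0$
on the axis is approximately
$\lambda_0 + M\sigma^2 / (2 \lambda_0 \lVert v_2 - v_1 \rVert^2)$ — a chi
statistic's bias. At the synthetic generator's geometry (40 C-alpha
nodes, axis norm around 17 Å) and 0.5 Å noise this bias is on the order
of 0.05–0.15, which is visible in the norm-ratio series that stage 2 of
the analysis reports. The package therefore also provides
`method = "projection"`: the signed component of $v - v_1$ along the
axis, normalized by the axis norm. The projection is unbiased under
isotropic noise (the orthogonal noise components cancel in expectation)
and is the estimator used for parameter-recovery checks; the norm ratio
remains the default because it is the definition. Both are reported side
by side by the analysis scripts.

## Distance fluctuations and clustering

The distance-fluctuation matrix entry $\tau_{ij}$ is the population
variance over frames of the internal distance $d_{ij}$ between selected
atoms. Internal distances are invariant under per-frame rigid motion, so
no superposition is performed and the matrix is independent of any
reference structure; the diagonal is exactly zero. The variance is
accumulated in two passes (mean first, then squared deviations) because
the fluctuations of interest can be ten orders of magnitude smaller than
the distances themselves and the one-pass formula loses them to
cancellation.

Trajectory clustering follows the GROMOS scheme: on the matrix of
pairwise least-squares-superposed RMSD values, the frame with the most
neighbors within the cutoff (default 1.5 Å) becomes a centroid, its
neighborhood is removed, and the procedure recurs. Ties in neighbor count
are broken toward the lowest frame index so results are deterministic.
The cutoff is the only parameter; the number of clusters is emergent —
the unimodal synthetic trajectories legitimately collapse into a single
cluster at the default noise level, unlike multi-basin trajectories of a
real protein.

## Elastic-network normal modes

The normal-mode module builds an anisotropic network model on the
C-alpha nodes: harmonic springs of uniform constant $k$ between all node
pairs within a 15 Å cutoff, with Hessian super-blocks
$-k\,\Delta r \Delta r^{\mathsf T} / |\Delta r|^2$ off the diagonal and
negative row-sums on it. Rigid translations and rotations are exact zero
modes; `compute_modes()` identifies them by relative eigenvalue threshold
($10^{-8}$ of the largest) and asserts that exactly six fall below it
before returning the requested number of low-frequency modes. $k$ is
arbitrary (mode shapes and relative frequencies are what matter), the
cutoff is the conventional 15 Å of C-alpha network models. Overlaps
between eigenvectors and the open-to-locked difference vector quantify
how much of the transition the harmonic modes capture; for the synthetic
90-degree domain rotation that overlap is modest, as expected for a
strongly anharmonic motion evaluated in a single-state network.

## MM/PBSA energetics

Binding free energies follow the end-point decomposition
$\Delta G_{\mathrm{binding}} = G_{\mathrm{complex}} -
(G_{\mathrm{protein}} + G_{\mathrm{ligand}})$ with each $G_x$ the sum of
molecular-mechanics terms (bonded, Lennard-Jones, Coulomb) and solvation
terms (Poisson-Boltzmann polar, surface-area nonpolar). Key choices:

* **Single-trajectory protocol.** The unbound partner geometries are
  extracted unchanged from the complex, so bonded terms cancel exactly in
  the difference and the MM deltas reduce to the cross-group
  interactions. The reference study re-ran short MD after mutation; this
  package re-evaluates single geometries or frame ensembles instead — a
  documented substitution, since running MD is out of its scope.
* **Entropy off by default.** The ledger carries a $-TS$ slot, but totals
  sum exactly the four component terms; that convention reproduces the
  arithmetic of published MM/PBSA component tables for this system class.
* **No nonbonded cutoff.** All-pairs exact sums (the systems scored here
  are small, and exactness is what the oracle tests check); solute
  dielectric 2, solvent 80, 150 mM monovalent salt, 300 K.
* **Per-residue decomposition.** Pairwise MM cross energies are split
  half to each partner atom; the polar term per atom is
  $\tfrac12 q_i (\phi^{\mathrm{complex}}_i - \phi^{\mathrm{free}}_i)$;
  the nonpolar term per atom is $\gamma\,\Delta\mathrm{SASA}_i$ with the
  constant offset's net effect spread uniformly over atoms. Per-atom
  values sum to per-residue values and to the total delta exactly (the
  test suite checks closure to $10^{-6}$ kcal/mol).
* **Alanine scanning.** Side chains are truncated beyond the beta carbon;
  the beta carbon is retyped with its charge set to neutralize the
  residue. Glycine and proline are rejected. A multi-site mutant is one
  call with several residues.

### The Poisson-Boltzmann solver

The polar term solves the linearized PB equation by finite differences on
a cubic grid: solute dielectric inside atom radii, solvent outside
(harmonic-mean face dielectrics), Debye screening active outside a 2 Å
Stern layer, trilinear charge spreading, Debye–Hückel Dirichlet boundary
values, and a Jacobi-preconditioned conjugate-gradient solve warm-started
from the boundary field. The reaction-field energy subtracts a
uniform-dielectric reference solved on the identical grid, which cancels
the grid self-energy exactly. Defaults: 0.5 Å spacing, 8 Å padding.
Against the Born ion closed form the solver is within about 4 % at 0.5 Å
spacing, with the error shrinking monotonically from 2 Å through 1 Å to
0.5 Å; potentials are carried in kcal/mol/e and converted to $k_BT/e$
(0.596 kcal/mol at 300 K) where surfaces are mapped.

The nonpolar term is $\gamma \cdot \mathrm{SASA} + b$ with the common
parameterization $\gamma = 0.00542$ kcal/(mol Å$^2$), $b = 0.92$
kcal/mol, probe 1.4 Å. SASA is Shrake–Rupley with a deterministic
golden-spiral point set (960 points per atom by default); the isolated
atom reproduces $4\pi(r+p)^2$ to well under 0.5 %.

## Synthetic data: what it emulates and what it does not

The generators are pure functions of their specification (seed included).

* `make_two_state_references()` builds two compact helical domains and
  produces the locked state by rotating the C-domain about its long
  principal axis (default 90°) and translating it toward the N-domain
  (default 3 Å) — the qualitative open-to-locked rearrangement of a
  two-domain adaptor subunit. Defaults of 20+20 residues keep every
  eigen-decomposition and clustering run desk-scale.
* `make_trajectory()` places frames at a target lambda on the reference
  axis plus isotropic Gaussian noise (default 0.5 Å, a typical
  backbone-fluctuation scale) and then scatters each frame with a random
  rigid pose so that superposition is always exercised. Targets 0.24,
  0.32 and 0.65 in the analysis scripts mirror the unbound, needle-bound
  and sphere-bound regimes of the motivating system.
* `make_particle()` carves sites from a cell-centered cubic lattice
  (default 2 Å spacing) clipped to the shape and assigns charges by
  declarative region patterns: spheres alternate weak-positive /
  strong-negative surface sites along a surface sweep with balanced
  counts (so total charge tracks surface area and the charge density of
  a size series stays nearly constant, within about 8 % across 1.6–2.4
  nm); needles carry positive tips (outer sixth of the length) on a
  negative body; rods are weakly positive. The default sphere diameter is
  1.926 nm. Aspect ratios 3:1 (rod) and 8:1 (needle) are conventions.
* `make_complex()` is the energetics fixture: a net-neutral 24-residue
  helical peptide (five basic, five acidic residues) with a neutral
  Janus-charged 1 nm particle docked against its acidic face. Net
  neutrality makes far-separated interaction energies vanish to below
  $10^{-3}$ kcal/mol, and the opposite-sign interface keeps the bound
  state attractive (about −9 kcal/mol of cross Coulomb energy).

What passing tests on these stand-ins show is that the *machinery* is
correct: identities hold, oracles agree, parameters are recovered. They
do not show that real MD ensembles of the real protein would reproduce
any published number — absolute binding energies in particular depend on
the original trajectories, force field and PB parameterization, none of
which are reconstructed here.

## Numerical choices and degenerate inputs

* Superposition requires three non-collinear selected atoms; collinear
  or coincident geometry is an error, as are insertion codes in PDB
  input (first alternate locations are kept).
* Population (not sample) variance in the fluctuation matrix, matching
  the time-average semantics of the definition.
* Clustering tie-break: lowest frame index. Eigenvalue ties in the mode
  set keep LAPACK's deterministic ordering.
* The PB solver fails loudly (with the residual) if conjugate gradients
  do not converge within the iteration budget, and errors if an atom
  leaves the grid.
* Missing per-atom parameters are tolerated by geometry-only operations
  and raised as errors by the first energetics operation that touches
  the atom, naming it.
* Analysis problem sizes (100-frame trajectories, 0.8 Å PB grids for the
  fixture complex, 240-point SASA in the drivers) are chosen so the full
  workflow runs in about a minute on a laptop core; the defaults inside
  the package (0.5 Å, 960 points) are the accuracy-first settings used
  by the validation suite where it matters.

## Known limitations

* The "principal component" here is the printed norm-ratio coordinate,
  not an eigen-decomposition of a covariance matrix; free-energy surfaces
  along lambda are out of scope.
* Nonlinear PB, generalized-Born approximations, explicit solvent and
  entropy estimation are not implemented; the entropy slot exists only so
  the ledger can carry a known value.
* Nanoparticles are fixed point-charge site models; no quantum-derived
  charges, no ion release, no crystal-face chemistry.
* The alanine scan re-scores a fixed geometry; it does not relax the
  mutant.
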