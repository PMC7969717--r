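# hapbind

Analysis toolkit for the binding of small charged nanoparticles —
hydroxyapatite-like spheres, rods and needles — to a two-domain
cargo-binding protein such as the mu2 subunit of the AP2 clathrin
adaptor. Nanoparticles of different morphology carry different
electrostatic surface patterns, bind different faces of the protein, and
push it by different amounts along its open-to-locked conformational
transition; this package implements the full post-simulation analysis
chain with which such a study quantifies those effects, for
computational structural biologists who want the machinery without the
original trajectories.

What it computes:

* **Transition coordinate lambda** between an open reference `v1`
  (lambda = 0) and a locked reference `v2` (lambda = 1):
  `lambda = |v - v1| / |v2 - v1|` over the C-alpha coordinate vector of
  a frame superposed onto the open state, plus an unbiased projection
  variant.
* **Distance-fluctuation matrix** `tau_ij = <(d_ij - <d_ij>)^2>`, the
  per-pair time variance of internal C-alpha distances —
  reference-structure-free plasticity.
* **GROMOS clustering** of trajectories on pairwise superposed RMSD with
  a 1.5 Å criterion.
* **Elastic-network normal modes** (anisotropic network model on
  C-alpha nodes, 15 Å cutoff) and mode overlaps with the open-to-locked
  difference vector.
* **MM/PBSA binding energies**
  `dG_bind = G_complex - (G_protein + G_ligand)` with
  `G = E_bonded + E_vdW + E_elec + G_polar + G_nonpolar`: all-pairs
  Coulomb and Lennard-Jones, a finite-difference linearized
  Poisson-Boltzmann polar term, a Shrake-Rupley surface-area nonpolar
  term, per-residue decomposition that sums exactly to the total, and
  computational alanine scanning.
* **Nanoparticle surface maps**: accessible-surface electrostatic
  potentials in kBT/e, sign-patch classification, and charge-density
  constancy across particle sizes.

A seeded synthetic-data module generates two-state references,
lambda-targeted noisy trajectories, patterned sphere/rod/needle
particles and a fully parameterized protein-particle complex, so the
whole pipeline runs from scratch with known ground truth.

## Worked example

```r
library(hapbind)

refs <- make_two_state_references(two_state_spec(seed = 1))
refs
#> ReferencePair: open/locked states, 160 atoms, calpha selection (40 atoms), axis norm 17.01 A

traj <- make_trajectory(refs, trajectory_spec(lambda_target = 0.65,
                                              n_frames = 100, seed = 2))
lambda_series(traj, refs)
#> LambdaSeries: 100 frames, mean lambda = 0.7190 (norm)
lambda_series(traj, refs, method = "projection")
#> LambdaSeries: 100 frames, mean lambda = 0.6456 (projection)

fx <- make_complex(seed = 1)
cfg <- energy_config(pb_grid_spacing = 0.8, pb_grid_pad = 6,
                     sasa_points = 240)
mmpbsa(fx$complex, fx$protein_idx, fx$ligand_idx, fx$terms, cfg)
#> MM/PBSA binding energy (delta = complex - protein - ligand):
#> E_bonded          0.0000 kcal/mol
#> E_vdW            -0.1647 kcal/mol
#> E_elec           -8.8283 kcal/mol
#> G_polar           3.3171 kcal/mol
#> G_nonpolar       -0.9200 kcal/mol
#> G_total          -6.5959 kcal/mol
#> top contributing residues:
#>   chain resid resname       elec           vdw      polar     nonpolar      total
#> 1     A    16     GLU -6.7962746 -0.0070412191  5.5300446 -0.035384615 -1.3086558
#> ...
```

Reading the numbers: the trajectory was generated at a target lambda of
0.65 (the "sphere-bound, mostly locked" regime); the norm-ratio mean
overshoots to 0.719 because that estimator is biased upward by
positional noise, while the projection variant recovers 0.646. The
synthetic complex binds its particle at −6.6 kcal/mol, dominated by the
attractive cross electrostatics (−8.8) against a desolvation penalty
(+3.3); GLU16 is the top contributing residue, and
`alanine_scan(fx$complex, list("A:16"), ...)` confirms that truncating
it costs about 1.4 kcal/mol of binding.

## The analysis workflow

The numbered drivers under `analysis/` run the full analysis sequence
and write TSV tables (with provenance headers) under `results/`:

```sh
Rscript analysis/01_simulate.R      # references, trajectories, particles, complex
Rscript analysis/02_conformation.R  # lambda series, clusters, fluctuation matrices
Rscript analysis/03_modes.R         # elastic-network modes and overlaps
Rscript analysis/04_energetics.R    # MM/PBSA, per-residue table, alanine scan
Rscript analysis/05_surface.R       # particle EPS maps, patches, size series
```

`run_pipeline(run_config(...))` performs the same sequence as a single
library call and is byte-reproducible under a fixed config and seed.

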