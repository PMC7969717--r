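#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study systems.
#
# Builds the open/locked two-state reference pair, three trajectories
# whose transition-coordinate targets mirror the three binding regimes
# (unbound ~0.24, needle-bound ~0.32, sphere-bound ~0.65), the three
# particle morphologies, and the small protein-particle complex used for
# the binding-energy stages. Everything is written as plain PDB/XYZ +
# parameter sidecars under results/sim/ so later stages can run from
# files alone.

suppressMessages(library(hapbind))

seed <- 1
outdir <- "results/sim"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

refs <- make_two_state_references(two_state_spec(seed = seed))
write_structure(refs$v1, file.path(outdir, "open.pdb"))
write_structure(refs$v2, file.path(outdir, "locked.pdb"))
message("references: ", n_atoms(refs$v1), " atoms, lambda axis norm ",
        round(refs$axis_norm, 2), " A over the C-alpha selection")

targets <- c(apo = 0.24, needle = 0.32, sphere = 0.65)
for (nm in names(targets)) {
  traj <- make_trajectory(refs, trajectory_spec(targets[[nm]],
                                                positional_noise_sd = 0.5,
                                                n_frames = 100,
                                                seed = seed + match(nm, names(targets))))
  write_trajectory(traj, file.path(outdir, paste0("traj_", nm, ".pdb")))
  message("trajectory '", nm, "': 100 frames at lambda target ",
          targets[[nm]])
}

for (sh in c("sphere", "rod", "needle")) {
  p <- make_particle(particle_spec(sh, seed = seed))
  sites <- p$sites
  s <- new_structure(data.frame(
    name = "SIT", element = "X", resid = seq_len(nrow(sites)),
    resname = "NP", chain = "A", x = sites$x, y = sites$y, z = sites$z,
    charge = sites$charge))
  write_structure(s, file.path(outdir, paste0("particle_", sh, ".xyz")))
  write_parameters(data.frame(chain = "A", resid = seq_len(nrow(sites)),
                              atom = "SIT", charge = sites$charge,
                              sigma = 3.4, epsilon = 0.1, radius = 1.7),
                   file.path(outdir, paste0("particle_", sh, ".prm")))
  message(sh, " particle: ", nrow(sites), " sites, net charge ",
          round(total_charge(p), 1), " e")
}

fx <- make_complex(seed = seed)
write_structure(fx$complex, file.path(outdir, "complex.pdb"))
write_parameters(fx$complex, file.path(outdir, "complex.prm"))
message("complex fixture: ", n_atoms(fx$complex), " atoms (protein ",
        length(fx$protein_idx), " + particle ", length(fx$ligand_idx), ")")
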