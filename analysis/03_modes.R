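#!/usr/bin/env Rscript
# Stage 3: elastic-network normal modes of the open state.
#
# An anisotropic network model (15 A cutoff, uniform springs) on the
# C-alpha nodes yields the low-frequency collective motions; the first
# five non-trivial modes are reported with their per-node amplitudes and
# their overlap with the open-to-locked difference vector.

suppressMessages(library(hapbind))

simdir <- "results/sim"
outdir <- "results/modes"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
cfg <- run_config(list(outdir = outdir, log_level = "quiet"))

open <- read_structure(file.path(simdir, "open.pdb"))
locked <- read_structure(file.path(simdir, "locked.pdb"))
refs <- reference_pair(open, locked)

model <- build_enm(open, cutoff = 15, k = 1)
modes <- compute_modes(model, n_modes = 5)
ov <- mode_overlap(modes, refs)

write_output_table(data.frame(mode = 1:5, eigenvalue = modes$eigenvalues,
                              overlap_open_to_locked = ov),
                   file.path(outdir, "modes.tsv"), cfg)
amp <- sapply(1:5, function(m) mode_amplitudes(modes, m))
resid <- open$atoms$resid[model$node_idx]
write_output_table(data.frame(resid = resid, amp),
                   file.path(outdir, "mode_amplitudes.tsv"), cfg)

n_half <- max(resid) / 2
for (m in 1:5) {
  rN <- mean(amp[resid <= n_half, m]^2)
  rC <- mean(amp[resid > n_half, m]^2)
  message(sprintf(
    "mode %d: eigenvalue %.3f, overlap %.3f, C/N amplitude ratio %.2f",
    m, modes$eigenvalues[m], ov[m], rC / rN))
}
message(sprintf(
  "cumulative squared overlap of the first five modes with the transition: %.2f",
  sum(ov^2)))
message("the soft modes redistribute amplitude between the two domains; ",
        "overlap with the 90-degree domain rotation is modest, as that ",
        "motion is far outside the harmonic regime of a single-state ",
        "network")
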