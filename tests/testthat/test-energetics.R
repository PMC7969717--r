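two_atoms <- function(r, q1, q2, sigma = 3, eps = 0.1) {
  new_structure(data.frame(
    name = c("A1", "A2"), element = "X", resid = 1:2, resname = "UNK",
    chain = "A", x = c(0, r), y = 0, z = 0, charge = c(q1, q2),
    sigma = sigma, epsilon = eps, radius = 1.5))
}

test_that("Coulomb energies reproduce the defining constant and the
           brute-force pair sum", {
  cfg1 <- energy_config(solute_dielectric = 1)
  expect_equal(coulomb_energy(two_atoms(1, 1, 1), cfg1), 332.0636,
               tolerance = 1e-10)
  cfg2 <- energy_config(solute_dielectric = 2)
  expect_equal(coulomb_energy(two_atoms(2, 1, -1), cfg2), -83.0159,
               tolerance = 1e-4)
  for (seed in 1:3) {
    s <- random_structure(20, seed = seed)
    expect_equal(coulomb_energy(s, cfg2),
                 brute_coulomb(s, eps = 2), tolerance = 1e-10)
    ia <- 1:8; ib <- 9:20
    expect_equal(coulomb_energy(s, cfg2, ia, ib),
                 brute_coulomb(s, eps = 2, ia, ib), tolerance = 1e-10)
  }
  s <- random_structure(5, seed = 1)
  s$atoms$charge[3] <- NA
  expect_error(coulomb_energy(s, cfg1), "no charge")
  expect_error(coulomb_energy(s, cfg1, 1:3, 2:4), "overlap")
})

test_that("Lennard-Jones energy has its zero crossing at sigma, minimum of
           -epsilon, and matches the brute-force sum", {
  cfg <- energy_config()
  expect_equal(lj_energy(two_atoms(3, 0, 0, sigma = 3, eps = 0.2), cfg), 0,
               tolerance = 1e-12)
  expect_equal(lj_energy(two_atoms(2^(1 / 6) * 3, 0, 0, sigma = 3,
                                   eps = 0.2), cfg),
               -0.2, tolerance = 1e-12)
  # combining rules across unlike atoms
  s <- two_atoms(3.25, 0, 0)
  s$atoms$sigma <- c(3, 3.5); s$atoms$epsilon <- c(0.1, 0.4)
  expect_equal(lj_energy(s, cfg), 0, tolerance = 1e-12)  # r = mean sigma
  for (seed in 4:6) {
    sr <- random_structure(20, seed = seed, spread = 10)
    expect_equal(lj_energy(sr, cfg), brute_lj(sr), tolerance = 1e-10)
  }
})

test_that("bonded terms vanish at equilibrium and match a direct
           evaluation on a strained molecule", {
  s <- random_structure(4, seed = 3, spread = 3)
  xyz <- coords(s)
  r12 <- sqrt(sum((xyz[1, ] - xyz[2, ])^2))
  tm0 <- bonded_terms(bonds = data.frame(i = 1, j = 2, kb = 100, r0 = r12))
  expect_equal(bonded_energy(s, tm0), 0, tolerance = 1e-12)
  # angle at theta0 and a zero-constant dihedral contribute nothing
  u <- xyz[1, ] - xyz[2, ]; v <- xyz[3, ] - xyz[2, ]
  th <- acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
  tm1 <- bonded_terms(
    angles = data.frame(i = 1, j = 2, k = 3, ktheta = 40, theta0 = th),
    dihedrals = data.frame(i = 1, j = 2, k = 3, l = 4, kphi = 0, n = 2,
                           delta = 0))
  expect_equal(bonded_energy(s, tm1), 0, tolerance = 1e-10)
  # strained terms against a hand-computed sum
  tm2 <- bonded_terms(
    bonds = data.frame(i = c(1, 2), j = c(2, 3), kb = c(100, 50),
                       r0 = c(r12 - 0.2, 1.0)),
    angles = data.frame(i = 1, j = 2, k = 3, ktheta = 40, theta0 = th - 10),
    dihedrals = data.frame(i = 1, j = 2, k = 3, l = 4, kphi = 1.5, n = 3,
                           delta = 30))
  r23 <- sqrt(sum((xyz[2, ] - xyz[3, ])^2))
  phi <- local({
    b1 <- xyz[2, ] - xyz[1, ]; b2 <- xyz[3, ] - xyz[2, ]
    b3 <- xyz[4, ] - xyz[3, ]
    n1 <- pracma::cross(b1, b2); n2 <- pracma::cross(b2, b3)
    m1 <- pracma::cross(n1, b2 / sqrt(sum(b2^2)))
    atan2(sum(m1 * n2), sum(n1 * n2))
  })
  expected <- 100 * 0.2^2 + 50 * (r23 - 1)^2 + 40 * (10 * pi / 180)^2 +
    1.5 * (1 + cos(3 * phi - 30 * pi / 180))
  expect_equal(bonded_energy(s, tm2), expected, tolerance = 1e-8)
  # degenerate geometry rejected
  s2 <- s; s2$atoms$x[2] <- s2$atoms$x[1]
  s2$atoms$y[2] <- s2$atoms$y[1]; s2$atoms$z[2] <- s2$atoms$z[1]
  expect_error(bonded_energy(s2, tm1), "ngle|oincident")
})

test_that("SASA reproduces the closed form, is additive for distant atoms,
           and agrees with a 10x denser sampling for a fused dimer", {
  cfg <- energy_config()
  iso <- two_atoms(50, 0, 0)
  iso$atoms$radius <- c(1.8, 1.2)
  sa <- sasa(iso, cfg)
  exact <- 4 * pi * ((1.8 + 1.4)^2 + (1.2 + 1.4)^2)
  expect_equal(sa$total, exact, tolerance = 0.005)
  expect_equal(sa$per_atom[1], 4 * pi * 3.2^2, tolerance = 0.005 * 4 * pi * 3.2^2)
  # fused dimer vs denser-point evaluation
  dim2 <- two_atoms(1.9, 0, 0); dim2$atoms$radius <- c(1.8, 1.5)
  coarse <- sasa(dim2, cfg)
  dense <- sasa(dim2, energy_config(sasa_points = 9600))
  expect_equal(coarse$total, dense$total,
               tolerance = 0.01 * dense$total / coarse$total)
  # monotone decrease on approach
  areas <- vapply(c(6, 4, 3, 2.5), function(r)
    sasa(two_atoms(r, 0, 0), cfg)$total, numeric(1))
  expect_true(all(diff(areas) <= 0))
  bad <- two_atoms(3, 0, 0); bad$atoms$radius <- NA
  expect_error(sasa(bad, cfg), "radius")
})

test_that("the PB solver is zero for uncharged solutes and approximates the
           Born ion", {
  cfg <- energy_config(solute_dielectric = 1, ionic_strength = 0,
                       pb_grid_spacing = 1.0, pb_grid_pad = 6)
  s0 <- two_atoms(3, 0, 0)
  expect_identical(pb_polar_energy(s0, cfg), 0)
  ion <- new_structure(data.frame(
    name = "ION", element = "X", resid = 1, resname = "ION", chain = "A",
    x = 0, y = 0, z = 0, charge = 1, sigma = 3, epsilon = 0.1, radius = 2))
  g <- pb_polar_energy(ion, cfg)
  born <- -(332.0636 / 2) * (1 / 2) * (1 / 1 - 1 / 80)
  expect_equal(g, born, tolerance = 0.08)   # coarse grid smoke check
})

test_that("binding deltas obey the definition, decomposition closes, and
           the noninteracting limit vanishes", {
  fx <- make_complex(seed = 2)
  cfg <- energy_config(pb_grid_spacing = 1.0, pb_grid_pad = 5,
                       sasa_points = 240)
  r <- mmpbsa(fx$complex, fx$protein_idx, fx$ligand_idx, fx$terms, cfg)
  # (tolerance allows float reassociation: the internal MM sums are many
  # orders larger than the cross terms they cancel against)
  for (t in c("E_bonded", "E_vdW", "E_elec", "G_polar", "G_nonpolar",
              "G_total"))
    expect_equal(r$delta[[t]],
                 r$complex[[t]] - r$protein[[t]] - r$ligand[[t]],
                 tolerance = 1e-6)
  expect_identical(r$delta$E_bonded, 0)
  expect_equal(sum(r$per_residue$total), r$delta$G_total, tolerance = 1e-6)
  expect_equal(sum(r$per_atom$total), r$delta$G_total, tolerance = 1e-6)
  # cross-term oracle: delta E_elec equals the independent cross Coulomb
  expect_equal(r$delta$E_elec,
               brute_coulomb(fx$complex, eps = 2, fx$protein_idx,
                             fx$ligand_idx), tolerance = 1e-9)
  # swapping the partner labels leaves the binding energy unchanged
  r_swap <- mmpbsa(fx$complex, fx$ligand_idx, fx$protein_idx, fx$terms, cfg)
  expect_equal(r_swap$delta$G_total, r$delta$G_total, tolerance = 1e-9)
  # translating the ligand far away kills the MM interaction terms
  far <- fx$complex
  xyz <- coords(far)
  xyz[fx$ligand_idx, 1] <- xyz[fx$ligand_idx, 1] + 500
  far <- set_coords(far, xyz)
  expect_lt(abs(coulomb_energy(far, cfg, fx$protein_idx, fx$ligand_idx)),
            1e-3)
  expect_lt(abs(lj_energy(far, cfg, fx$protein_idx, fx$ligand_idx)), 1e-3)
  expect_error(mmpbsa(fx$complex, fx$protein_idx,
                      c(fx$protein_idx[1], fx$ligand_idx), fx$terms, cfg),
               "overlap")
})

test_that("trajectory averaging reports per-frame values and their mean", {
  fx <- make_complex(seed = 3)
  cfg <- energy_config(pb_grid_spacing = 1.2, pb_grid_pad = 5,
                       sasa_points = 120)
  xyz0 <- coord_vector(fx$complex)
  set.seed(99)
  traj <- new_trajectory(fx$complex,
                         rbind(xyz0, xyz0 + rnorm(length(xyz0), 0, 0.05)))
  out <- mmpbsa_trajectory(traj, fx$protein_idx, fx$ligand_idx, fx$terms,
                           cfg)
  expect_equal(nrow(out$per_frame), 2)
  g <- out$summary[out$summary$term == "G_total", ]
  expect_equal(g$mean, mean(out$per_frame$G_total), tolerance = 1e-12)
  expect_equal(g$sd, sd(out$per_frame$G_total), tolerance = 1e-12)
})

test_that("alanine truncation is a no-op on alanine, matches the
           charge-removal oracle, and a quadruple equals one call", {
  fx <- make_complex(seed = 1)
  cfg <- energy_config(pb_grid_spacing = 1.0, pb_grid_pad = 5,
                       sasa_points = 240)
  # residue 5 is alanine in the fixture sequence
  expect_identical(fx$complex$atoms$resname[fx$complex$atoms$resid == 5 &
                                              fx$complex$atoms$chain == "A"][1],
                   "ALA")
  sc <- alanine_scan(fx$complex, list("A:5"), fx$protein_idx,
                     fx$ligand_idx, fx$terms, cfg)
  expect_equal(sc$ddG$ddG[1], 0, tolerance = 1e-8)
  # charged-residue truncation: the change in delta E_elec equals the
  # cross-Coulomb contribution of the deleted/neutralized charges
  m <- ala_mutate(fx$complex, "A:2")       # lysine
  keep <- m$kept
  map <- integer(n_atoms(fx$complex)); map[keep] <- seq_along(keep)
  r_wt <- mmpbsa(fx$complex, fx$protein_idx, fx$ligand_idx, fx$terms, cfg)
  r_mut <- mmpbsa(m$structure, map[intersect(fx$protein_idx, keep)],
                  map[intersect(fx$ligand_idx, keep)], NULL, cfg)
  # oracle: recompute both cross Coulomb sums independently
  oracle_wt <- brute_coulomb(fx$complex, eps = 2, fx$protein_idx,
                             fx$ligand_idx)
  oracle_mut <- brute_coulomb(m$structure, eps = 2,
                              map[intersect(fx$protein_idx, keep)],
                              map[intersect(fx$ligand_idx, keep)])
  expect_equal(r_mut$delta$E_elec - r_wt$delta$E_elec,
               oracle_mut - oracle_wt, tolerance = 1e-9)
  # glycine has no beta carbon
  expect_error(ala_mutate(fx$complex, "A:15"), "glycine")
  expect_error(ala_mutate(fx$complex, "A:99"), "not found")
  # simultaneous quadruple = one call with four residues (definition)
  quad <- c("A:2", "A:6", "A:9", "A:13")
  sc_q <- alanine_scan(fx$complex, list(quad), fx$protein_idx,
                       fx$ligand_idx, fx$terms, cfg)
  m4 <- ala_mutate(fx$complex, quad)
  keep4 <- m4$kept
  map4 <- integer(n_atoms(fx$complex)); map4[keep4] <- seq_along(keep4)
  direct <- mmpbsa(m4$structure, map4[intersect(fx$protein_idx, keep4)],
                   map4[intersect(fx$ligand_idx, keep4)],
                   NULL, cfg)
  expect_equal(sc_q$ddG$dG_mutant[1], direct$delta$G_total,
               tolerance = 1e-9)
})

test_that("the energy ledger aggregates its terms exactly, with entropy
           only when switched on", {
  eb <- energy_breakdown(1.5, -2.25, 10, -3, 0.5, TS = 4)
  expect_equal(eb$G_total, 1.5 - 2.25 + 10 - 3 + 0.5, tolerance = 1e-12)
  eb2 <- energy_breakdown(1.5, -2.25, 10, -3, 0.5, TS = 4,
                          include_entropy = TRUE)
  expect_equal(eb2$G_total, eb$G_total - 4, tolerance = 1e-12)
})
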