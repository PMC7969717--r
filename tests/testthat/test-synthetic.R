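test_that("two-state generator is a pure function of its spec", {
  a <- make_two_state_references(two_state_spec(5, 5, 90, 3, seed = 1))
  b <- make_two_state_references(two_state_spec(5, 5, 90, 3, seed = 1))
  expect_identical(coords(a$v1), coords(b$v1))
  expect_identical(coords(a$v2), coords(b$v2))
  c2 <- make_two_state_references(two_state_spec(5, 5, 90, 3, seed = 2))
  expect_false(identical(coords(a$v1), coords(c2$v1)))
})

test_that("the two states share atoms, differ only by the C-domain motion", {
  spec <- two_state_spec(6, 8, 60, 2, seed = 11)
  refs <- make_two_state_references(spec)
  expect_identical(refs$v1$atoms$name, refs$v2$atoms$name)
  n_dom <- which(refs$v1$atoms$resid <= spec$n_residues_N)
  expect_identical(coords(refs$v1)[n_dom, ], coords(refs$v2)[n_dom, ])
  c_dom <- which(refs$v1$atoms$resid > spec$n_residues_N)
  # C-domain moved rigidly: all internal distances preserved, coords differ
  expect_false(isTRUE(all.equal(coords(refs$v1)[c_dom, ],
                                coords(refs$v2)[c_dom, ])))
  d1 <- dist(coords(refs$v1)[c_dom, ])
  d2 <- dist(coords(refs$v2)[c_dom, ])
  expect_equal(as.numeric(d1), as.numeric(d2), tolerance = 1e-10)
})

test_that("degenerate two-state specs are rejected", {
  expect_error(two_state_spec(2, 5), "at least 3")
  expect_error(two_state_spec(rotation_angle = 0, translation = 0),
               "degenerate")
  expect_error(two_state_spec(rotation_angle = 200), "180")
})

test_that("lambda is 0 at the open and 1 at the locked reference", {
  for (seed in c(1, 7, 42)) {
    refs <- make_two_state_references(two_state_spec(seed = seed))
    expect_equal(compute_lambda(refs$v1, refs), 0, tolerance = 1e-10)
    expect_equal(compute_lambda(refs$v2, refs), 1, tolerance = 1e-10)
  }
})

test_that("noise-free trajectories sit exactly at the target lambda", {
  refs <- make_two_state_references(two_state_spec(seed = 5))
  tr <- make_trajectory(refs, trajectory_spec(0.5, 0, 4, seed = 1,
                                              rigid_scatter = FALSE))
  expect_equal(lambda_series(tr, refs)$values, rep(0.5, 4),
               tolerance = 1e-9)
  # with random rigid scatter, superposition restores the same value
  tr2 <- make_trajectory(refs, trajectory_spec(0.65, 0, 4, seed = 2,
                                               rigid_scatter = TRUE))
  expect_equal(lambda_series(tr2, refs)$values, rep(0.65, 4),
               tolerance = 1e-9)
})

test_that("noisy trajectory lambda matches a per-frame brute-force norm ratio", {
  refs <- make_two_state_references(two_state_spec(seed = 3))
  tr <- make_trajectory(refs, trajectory_spec(0.3, 0.5, 25, seed = 9))
  got <- lambda_series(tr, refs)
  idx <- apply_selection(refs$v1, refs$selection)
  v1 <- coord_vector(refs$v1, idx)
  dv <- coord_vector(refs$v2_aligned, idx) - v1
  expected <- vapply(seq_len(25), function(f) {
    fit <- superpose(get_frame(tr, f), refs$v1, refs$selection)$structure
    sqrt(sum((coord_vector(fit, idx) - v1)^2)) / sqrt(sum(dv^2))
  }, numeric(1))
  expect_equal(got$values, expected, tolerance = 1e-12)
  expect_equal(got$mean, mean(expected), tolerance = 1e-12)
})

test_that("particle generators respect pattern, determinism and scaling", {
  p1 <- make_particle(particle_spec("sphere", seed = 1))
  p2 <- make_particle(particle_spec("sphere", seed = 1))
  expect_identical(p1$sites, p2$sites)
  # uniform charge pattern -> total = n * q
  pu <- make_particle(particle_spec("sphere",
                                    site_charge_pattern = list(pos = 0.2,
                                                               neg = 0.2)))
  surf <- pu$sites$label != "interior"
  expect_equal(total_charge(pu), sum(surf) * 0.2, tolerance = 1e-12)
  expect_error(make_particle(particle_spec("sphere", lattice_spacing = 50)),
               "too large")
})

test_that("needle particles have positive tips and a negative body", {
  np <- make_particle(particle_spec("needle"))
  sp <- surface_points(np, density = 0.2)
  m <- electrostatic_map(np, sp)
  L <- 80                                   # 8 nm needle
  tip <- abs(sp$points[, 3]) > L / 2 * 2 / 3
  expect_gt(mean(m$potentials[tip]), 0)
  expect_lt(mean(m$potentials[!tip]), 0)
  expect_lt(total_charge(np), 0)
})

test_that("same-pattern spheres keep charge/area nearly constant", {
  specs <- lapply(c(1.6, 1.926, 2.4), function(d)
    particle_spec("sphere", characteristic_size = d))
  tab <- size_series_density(specs)
  expect_lt(attr(tab, "relative_spread"), 0.1)
  # area grows with diameter
  expect_true(all(diff(tab$area) > 0))
})

test_that("the complex fixture is deterministic, neutral-summed and bindable", {
  f1 <- make_complex(seed = 4)
  f2 <- make_complex(seed = 4)
  expect_identical(f1$complex$atoms, f2$complex$atoms)
  expect_equal(sum(f1$complex$atoms$charge),
               sum(f1$protein$atoms$charge) + total_charge(f1$particle),
               tolerance = 1e-9)
  # fully parameterized: no NA anywhere the energetics touches
  expect_false(anyNA(f1$complex$atoms$charge))
  expect_false(anyNA(f1$complex$atoms$sigma))
  expect_false(anyNA(f1$complex$atoms$radius))
  # attractive protein-particle electrostatics by construction
  cross <- coulomb_energy(f1$complex, energy_config(),
                          f1$protein_idx, f1$ligand_idx)
  expect_lt(cross, 0)
})
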