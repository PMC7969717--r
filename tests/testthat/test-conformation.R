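test_that("superposition recovers rigid motions and matches the quaternion
           closed form on random clouds", {
  s <- random_structure(10, seed = 2)
  expect_equal(superpose(s, s)$rmsd, 0, tolerance = 1e-12)
  moved <- rigid_move(s, seed = 3)
  fit <- superpose(moved, s)
  expect_lt(fit$rmsd, 1e-6)
  expect_equal(coords(fit$structure), coords(s), tolerance = 1e-6,
               ignore_attr = TRUE)
  for (seed in 1:5) {
    a <- random_structure(10, seed = seed)
    b <- random_structure(10, seed = seed + 100)
    expect_equal(superpose(a, b)$rmsd,
                 quaternion_rmsd(coords(a), coords(b)), tolerance = 1e-8)
  }
  tiny <- random_structure(2, seed = 1)
  expect_error(superpose(tiny, tiny), "3")
})

test_that("lambda is invariant under rigid motion of the frame and linear
           on the reference axis", {
  refs <- make_two_state_references(two_state_spec(seed = 8))
  x1 <- coords(refs$v1); x2 <- coords(refs$v2_aligned)
  for (t in c(0.25, 0.5, 0.8, 1.3)) {
    fr <- set_coords(refs$v1, x1 + t * (x2 - x1))
    expect_equal(compute_lambda(fr, refs), t, tolerance = 1e-9)
    expect_equal(compute_lambda(rigid_move(fr, seed = round(10 * t)), refs),
                 t, tolerance = 1e-9)
    expect_equal(compute_lambda(fr, refs, method = "projection"), t,
                 tolerance = 1e-9)
  }
  # off-axis structures: norm ratio >= |projection|
  off <- set_coords(refs$v1, x1 + 0.4 * (x2 - x1) +
                      matrix(rnorm(length(x1), 0, 0.4), ncol = 3))
  expect_gte(compute_lambda(off, refs),
             abs(compute_lambda(off, refs, method = "projection")))
  # degenerate axis rejected
  expect_error(reference_pair(refs$v1, refs$v1), "undefined")
})

test_that("a trajectory of open-state copies gives an all-zero series", {
  refs <- make_two_state_references(two_state_spec(6, 6, seed = 2))
  traj <- new_trajectory(refs$v1,
                         matrix(rep(coord_vector(refs$v1), 3), nrow = 3,
                                byrow = TRUE))
  ls <- lambda_series(traj, refs)
  expect_equal(ls$values, rep(0, 3), tolerance = 1e-9)
  expect_equal(ls$mean, 0, tolerance = 1e-9)
})

test_that("distance fluctuations match the brute-force variance and vanish
           for rigid trajectories", {
  refs <- make_two_state_references(two_state_spec(4, 4, seed = 6))
  # rigid trajectory: every frame a rigid copy -> all-zero matrix
  frames <- lapply(1:4, function(i) coord_vector(rigid_move(refs$v1, i)))
  rigid <- new_trajectory(refs$v1, do.call(rbind, frames))
  expect_lt(max(distance_fluctuation(rigid)$tau), 1e-18)

  # random 5-atom 50-frame trajectory vs direct variance
  set.seed(31)
  atoms <- random_structure(5, seed = 31)
  xyz <- matrix(rnorm(50 * 15, sd = 2), nrow = 50)
  xyz <- sweep(xyz, 2, coord_vector(atoms), "+")
  traj <- new_trajectory(atoms, xyz)
  fm <- distance_fluctuation(traj, selection_spec("all"))
  expect_equal(unname(fm$tau), brute_dfmat(traj, 1:5), tolerance = 1e-10)
  expect_true(isSymmetric(fm$tau))
  expect_true(all(diag(fm$tau) == 0))
  expect_true(all(fm$tau >= 0))
  expect_error(distance_fluctuation(new_trajectory(atoms, xyz[1, , drop = FALSE])),
               "2 frames")
})

test_that("two frames with distances a then b give tau = ((a-b)/2)^2", {
  atoms <- random_structure(2, seed = 1)
  xyz <- rbind(c(0, 0, 0, 3, 0, 0), c(0, 0, 0, 5, 0, 0))
  traj <- new_trajectory(atoms, xyz)
  fm <- distance_fluctuation(traj, selection_spec("all"))
  expect_equal(fm$tau[1, 2], 1, tolerance = 1e-12)   # ((3-5)/2)^2
})

test_that("distance fluctuations are reference-free: per-frame rigid motion
           leaves the matrix unchanged", {
  refs <- make_two_state_references(two_state_spec(4, 4, seed = 9))
  tr <- make_trajectory(refs, trajectory_spec(0.4, 0.3, 10, seed = 2,
                                              rigid_scatter = FALSE))
  scattered <- tr
  for (f in 1:10) {
    fr <- rigid_move(get_frame(tr, f), seed = 50 + f)
    scattered$xyz[f, ] <- coord_vector(fr)
  }
  expect_equal(distance_fluctuation(tr)$tau,
               distance_fluctuation(scattered)$tau, tolerance = 1e-8)
})

test_that("clustering partitions frames, respects the cutoff and matches
           the brute-force neighbor count", {
  refs <- make_two_state_references(two_state_spec(5, 5, seed = 12))
  # all frames identical -> one cluster
  same <- new_trajectory(refs$v1,
                         matrix(rep(coord_vector(refs$v1), 5), 5,
                                byrow = TRUE))
  cr <- cluster_trajectory(same, 1.5)
  expect_equal(length(cr$populations), 1)
  expect_equal(cr$populations, 1)

  # two planted bundles far apart -> two clusters with planted populations
  t1 <- make_trajectory(refs, trajectory_spec(0.05, 0.1, 12, seed = 3,
                                              rigid_scatter = FALSE))
  t2 <- make_trajectory(refs, trajectory_spec(0.95, 0.1, 8, seed = 4,
                                              rigid_scatter = FALSE))
  both <- new_trajectory(refs$v1, rbind(t1$xyz, t2$xyz))
  cr2 <- cluster_trajectory(both, 1.5, selection_spec("calpha"))
  expect_equal(cr2$populations, c(0.6, 0.4))
  expect_equal(length(unique(cr2$labels[1:12])), 1)
  expect_equal(length(unique(cr2$labels[13:20])), 1)
  # cutoff contract: every frame within cutoff of its centroid
  for (k in seq_along(cr2$centroids))
    expect_true(all(cr2$rmsd_matrix[cr2$centroids[k],
                                    cr2$labels == k] <= cr2$cutoff))

  # 20-frame mixed set vs literal reimplementation
  t3 <- make_trajectory(refs, trajectory_spec(0.5, 0.8, 20, seed = 5))
  cr3 <- cluster_trajectory(t3, 1.0, selection_spec("calpha"))
  expect_identical(cr3$labels, brute_gromos(cr3$rmsd_matrix, 1.0))
  expect_equal(sum(cr3$populations), 1, tolerance = 1e-12)
})
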