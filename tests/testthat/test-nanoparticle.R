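single_site <- function(q = 1) {
  new_nanoparticle(data.frame(x = 0, y = 0, z = 0, charge = q))
}

test_that("surface sampling covers isolated spheres and respects occlusion", {
  p <- single_site()
  sp <- surface_points(p, probe = 1.4, density = 1, site_radius = 1.5)
  r <- 1.5 + 1.4
  expect_equal(nrow(sp$points), round(4 * pi * r^2))
  expect_equal(sqrt(rowSums(sp$points^2)), rep(r, nrow(sp$points)),
               tolerance = 1e-9)
  expect_equal(sp$area, 4 * pi * r^2, tolerance = 1e-9)
  # two distant sites: two disjoint shells, additive area
  p2 <- new_nanoparticle(data.frame(x = c(0, 50), y = 0, z = 0,
                                    charge = c(1, -1)))
  sp2 <- surface_points(p2)
  expect_equal(sp2$area, 2 * 4 * pi * r^2, tolerance = 1e-6)
  # fused pair: no kept point lies inside the other site's sphere
  p3 <- new_nanoparticle(data.frame(x = c(0, 2), y = 0, z = 0,
                                    charge = c(1, 1)))
  sp3 <- surface_points(p3)
  for (i in 1:2) {
    others <- sp3$points[sp3$site != i, , drop = FALSE]
    cen <- as.numeric(p3$sites[i, c("x", "y", "z")])
    d <- sqrt(rowSums(sweep(others, 2, cen)^2))
    expect_true(all(d > r - 1e-9))
  }
})

test_that("surface potentials follow the Coulomb form in kBT/e", {
  p <- single_site(1)
  pts <- matrix(c(5, 0, 0), 1, 3)
  m <- electrostatic_map(p, pts, temperature = 300)
  kT300 <- 0.0019872041 * 300
  expect_equal(m$potentials, 332.0636 / (5 * kT300), tolerance = 1e-6)
  # all charges zero -> all potentials zero
  m0 <- electrostatic_map(single_site(0), pts)
  expect_equal(m0$potentials, 0)
  # linearity and sign symmetry on a random particle
  set.seed(5)
  sites <- data.frame(x = runif(10, -5, 5), y = runif(10, -5, 5),
                      z = runif(10, -5, 5), charge = runif(10, -1, 1))
  pr <- new_nanoparticle(sites)
  qpts <- matrix(runif(30, 8, 12), 10, 3)
  phi <- electrostatic_map(pr, qpts)$potentials
  brute <- vapply(seq_len(10), function(i) {
    sum(332.0636 * sites$charge /
          sqrt((qpts[i, 1] - sites$x)^2 + (qpts[i, 2] - sites$y)^2 +
               (qpts[i, 3] - sites$z)^2)) / kT300
  }, numeric(1))
  expect_equal(phi, brute, tolerance = 1e-10)
  neg <- new_nanoparticle(transform(sites, charge = -charge))
  expect_equal(electrostatic_map(neg, qpts)$potentials, -phi,
               tolerance = 1e-10)
  dbl <- new_nanoparticle(transform(sites, charge = 2 * charge))
  expect_equal(electrostatic_map(dbl, qpts)$potentials, 2 * phi,
               tolerance = 1e-10)
  expect_error(electrostatic_map(pr, as.matrix(sites[1, c("x", "y", "z")])),
               "coincides")
})

test_that("monopole potential decays as 1/d", {
  p <- single_site(1)
  d <- c(3, 6, 12)
  phi <- vapply(d, function(dd)
    electrostatic_map(p, matrix(c(dd, 0, 0), 1, 3))$potentials, numeric(1))
  expect_equal(phi[1] / phi[2], 2, tolerance = 1e-9)
  expect_equal(phi[2] / phi[3], 2, tolerance = 1e-9)
})

test_that("patch classification finds the planted sign layout", {
  # uniformly positive particle -> a single positive patch
  p <- make_particle(particle_spec("rod"))
  m <- electrostatic_map(p, surface_points(p, density = 0.15))
  pc <- classify_patches(m)
  expect_true(all(pc$labels %in% c("positive", "neutral")))
  expect_equal(sum(pc$patches$sign == "positive"), 1)
  # threshold above max|phi| -> everything neutral
  pc2 <- classify_patches(m, threshold = max(abs(m$potentials)) + 1)
  expect_true(all(pc2$labels == "neutral"))
  expect_equal(nrow(pc2$patches), 0)
  # needle: >= 2 positive patches at the extremal thirds of the long axis
  np <- make_particle(particle_spec("needle"))
  mn <- electrostatic_map(np, surface_points(np, density = 0.15))
  pcn <- classify_patches(mn)
  pos <- pcn$patches[pcn$patches$sign == "positive", ]
  expect_gte(nrow(pos), 2)
  L <- 80
  expect_true(all(abs(pos$cz) > L / 2 / 3))
  neg <- pcn$patches[pcn$patches$sign == "negative", ]
  expect_gte(nrow(neg), 1)
  expect_lt(min(abs(neg$cz)), L / 6)
})

test_that("size series report charge densities with their spread", {
  specs <- lapply(c(1.5, 2.1), function(d)
    particle_spec("sphere", characteristic_size = d))
  tab <- size_series_density(specs)
  expect_equal(nrow(tab), 2)
  # doubling every site charge doubles the density exactly
  specs2 <- lapply(specs, function(sp) {
    sp$site_charge_pattern <- lapply(sp$site_charge_pattern, `*`, 2)
    sp
  })
  tab2 <- size_series_density(specs2)
  expect_equal(tab2$charge_density, 2 * tab$charge_density,
               tolerance = 1e-12)
  expect_error(size_series_density(specs[1]), "at least 2")
  expect_error(size_series_density(list(specs[[1]],
                                        particle_spec("rod"))), "mixed")
})
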