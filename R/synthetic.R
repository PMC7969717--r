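# Seeded generators standing in for the study's MD/docking data: two-state
# protein references differing by a rigid domain motion, lambda-targeted
# trajectories with Gaussian positional noise, patterned charged particles
# (sphere / rod / needle), and a small fully parameterized protein-particle
# complex for the energetics engine.

rot_axis_angle <- function(axis, theta_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- theta_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  K <- matrix(c(0, -uz, uy, uz, 0, -ux, -uy, ux, 0), 3, 3, byrow = TRUE)
  diag(3) * ct + st * K + (1 - ct) * (u %o% u)
}

random_rotation_matrix <- function() {
  # uniform over SO(3) via a normalized Gaussian quaternion
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Specification of a synthetic two-state (open/locked) reference pair
#'
#' The generated protein has an N-terminal and a C-terminal domain; the
#' locked state differs from the open state only by a rigid motion of the
#' C-domain: a rotation about its long axis plus a translation toward the
#' N-domain, emulating the open-to-locked domain rearrangement of a
#' two-domain cargo-binding subunit.
#'
#' @param n_residues_N,n_residues_C domain sizes (residues, each >= 3)
#' @param rotation_angle rotation of the C-domain about its long axis
#'   \[degrees, in \(0, 180\]\ unless a nonzero translation is given\]
#' @param translation rigid approach of the C-domain toward the N-domain
#'   centroid \[Angstrom\]
#' @param seed integer seed (the generator is a pure function of the spec)
#' @return object of class `TwoStateSpec`
#' @export
two_state_spec <- function(n_residues_N = 20, n_residues_C = 20,
                           rotation_angle = 90, translation = 3, seed = 1) {
  if (n_residues_N < 3 || n_residues_C < 3)
    stop("both domains need at least 3 residues")
  if (rotation_angle < 0 || rotation_angle > 180)
    stop("rotation_angle must lie in [0, 180] degrees")
  if (rotation_angle == 0 && translation == 0)
    stop("degenerate spec: zero rotation and zero translation leave the ",
         "lambda axis undefined")
  structure(list(n_residues_N = n_residues_N, n_residues_C = n_residues_C,
                 rotation_angle = rotation_angle, translation = translation,
                 seed = as.integer(seed)), class = "TwoStateSpec")
}

# backbone (N, CA, C, O) helix for one domain; CA on an ideal helix, the
# other atoms at fixed local offsets. Returns a data.frame of atoms.
helix_domain <- function(n_res, resid_start, origin, resnames) {
  rise <- 1.5; radius <- 2.3; turn <- 100 * pi / 180
  rows <- list()
  for (i in seq_len(n_res)) {
    ang <- (i - 1) * turn
    ca <- origin + c(radius * cos(ang), radius * sin(ang), (i - 1) * rise)
    out <- c(cos(ang), sin(ang), 0)            # radially outward
    tang <- c(-sin(ang), cos(ang), 0)
    atoms <- rbind(
      N  = ca - 0.9 * tang - c(0, 0, 0.8),
      CA = ca,
      C  = ca + 0.9 * tang + c(0, 0, 0.7),
      O  = ca + 1.2 * tang + 1.0 * out + c(0, 0, 0.9))
    rid <- resid_start + i - 1
    rows[[i]] <- data.frame(
      name = rownames(atoms), element = substr(rownames(atoms), 1, 1),
      resid = rid, resname = resnames[(rid - 1) %% length(resnames) + 1],
      chain = "A", x = atoms[, 1], y = atoms[, 2], z = atoms[, 3],
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Generate an open/locked two-state reference pair
#'
#' Both states share the identical atom list; the N-domain coordinates are
#' bitwise identical between them and the C-domain of the locked state is a
#' rigid transform of the open one. By construction the transition
#' coordinate lambda is 0 at the open and 1 at the locked reference.
#'
#' @param spec a [two_state_spec()]
#' @return a `ReferencePair` (see [reference_pair()]) whose `v1` is the open
#'   and `v2` the locked structure
#' @export
make_two_state_references <- function(spec = two_state_spec()) {
  stopifnot(inherits(spec, "TwoStateSpec"))
  set.seed(spec$seed)
  resnames <- c("ALA", "GLU", "LYS", "SER", "LEU", "ASP", "GLN", "VAL")
  aN <- helix_domain(spec$n_residues_N, 1L, c(0, 0, 0), resnames)
  aC <- helix_domain(spec$n_residues_C, spec$n_residues_N + 1L,
                     c(12, 0, 0), resnames)
  # deterministic jitter so the domains are not perfectly regular helices
  jit <- function(df) {
    df$x <- df$x + rnorm(nrow(df), 0, 0.3)
    df$y <- df$y + rnorm(nrow(df), 0, 0.3)
    df$z <- df$z + rnorm(nrow(df), 0, 0.3)
    df
  }
  aN <- jit(aN); aC <- jit(aC)
  v1 <- new_structure(rbind(aN, aC),
                      metadata = list(state = "open", spec = spec))
  # locked state: rotate the C-domain about its long (principal) axis, then
  # translate it toward the N-domain centroid
  xyzC <- as.matrix(aC[, c("x", "y", "z")])
  cenC <- colMeans(xyzC)
  pc <- prcomp(xyzC, center = TRUE)
  axis <- pc$rotation[, 1]
  R <- rot_axis_angle(axis, spec$rotation_angle)
  xyzC2 <- sweep(sweep(xyzC, 2, cenC) %*% t(R), 2, cenC, "+")
  cenN <- colMeans(as.matrix(aN[, c("x", "y", "z")]))
  dirNC <- cenN - cenC
  dirNC <- dirNC / sqrt(sum(dirNC^2))
  xyzC2 <- sweep(xyzC2, 2, spec$translation * dirNC, "+")
  aC2 <- aC; aC2$x <- xyzC2[, 1]; aC2$y <- xyzC2[, 2]; aC2$z <- xyzC2[, 3]
  v2 <- new_structure(rbind(aN, aC2),
                      metadata = list(state = "locked", spec = spec))
  reference_pair(v1, v2, selection_spec("calpha"))
}

#' Specification of a lambda-targeted synthetic trajectory
#'
#' @param lambda_target target value of the transition coordinate in \[0, 1\]
#' @param positional_noise_sd isotropic Gaussian noise per coordinate
#'   \[Angstrom\]
#' @param n_frames number of frames (>= 1)
#' @param seed integer seed
#' @param rigid_scatter apply a random rigid rotation + translation to every
#'   frame (on by default so downstream superposition is always exercised)
#' @return object of class `TrajectorySpec`
#' @export
trajectory_spec <- function(lambda_target, positional_noise_sd = 0.5,
                            n_frames = 500, seed = 1, rigid_scatter = TRUE) {
  if (lambda_target < 0 || lambda_target > 1)
    stop("lambda_target must lie in [0, 1]")
  if (n_frames < 1) stop("n_frames must be >= 1")
  if (positional_noise_sd < 0) stop("positional_noise_sd must be >= 0")
  structure(list(lambda_target = lambda_target,
                 positional_noise_sd = positional_noise_sd,
                 n_frames = as.integer(n_frames), seed = as.integer(seed),
                 rigid_scatter = isTRUE(rigid_scatter)),
            class = "TrajectorySpec")
}

#' Generate a trajectory concentrated at a target lambda
#'
#' Frames are built on the reference axis as
#' `v1 + lambda_target * (v2_aligned - v1)` (all atoms), perturbed by
#' isotropic Gaussian noise, and then rigidly rotated/translated per frame
#' when `rigid_scatter` is on.
#'
#' @param refs a `ReferencePair`
#' @param spec a [trajectory_spec()]
#' @return a `Trajectory`
#' @export
make_trajectory <- function(refs, spec) {
  stopifnot(inherits(refs, "ReferencePair"), inherits(spec, "TrajectorySpec"))
  set.seed(spec$seed)
  x1 <- coords(refs$v1)
  x2 <- coords(refs$v2_aligned)
  base <- x1 + spec$lambda_target * (x2 - x1)
  n <- nrow(base)
  xyz <- matrix(NA_real_, spec$n_frames, 3L * n)
  for (f in seq_len(spec$n_frames)) {
    fr <- base + matrix(rnorm(3L * n, 0, spec$positional_noise_sd), n, 3)
    if (spec$rigid_scatter) {
      R <- random_rotation_matrix()
      tr <- runif(3, -20, 20)
      fr <- sweep(fr %*% t(R), 2, tr, "+")
    }
    xyz[f, ] <- as.vector(t(fr))
  }
  new_trajectory(refs$v1, xyz,
                 metadata = list(spec = spec, lambda_target = spec$lambda_target))
}

#' Specification of an idealized charged nanoparticle
#'
#' Interaction sites are carved from a regular cubic lattice clipped to the
#' shape, and charges are assigned by a declarative region pattern that
#' reproduces the qualitative surface-charge layouts of small
#' hydroxyapatite-like particles: spheres alternate weak-positive and
#' strong-negative surface sites, needles carry positive tips on a negative
#' body, rods are weakly positive overall.
#'
#' @param shape `"sphere"`, `"rod"` or `"needle"`
#' @param characteristic_size sphere diameter, or rod/needle length \[nm\].
#'   Defaults: sphere 1.926 nm; rod 3 nm (3:1 aspect); needle 8 nm
#'   (8:1 aspect).
#' @param lattice_spacing site lattice constant \[Angstrom\]
#' @param site_charge_pattern named list of region charges \[e\]; defaults
#'   per shape (see Details). Sphere: `pos`, `neg` (alternating surface
#'   sites); needle: `tip`, `body`, `tip_fraction`; rod: `surface`.
#'   Interior sites are neutral.
#' @param aspect_ratio length:width for rod/needle (ignored for spheres)
#' @param seed integer seed
#' @return object of class `ParticleSpec`
#' @export
particle_spec <- function(shape = c("sphere", "rod", "needle"),
                          characteristic_size = NULL, lattice_spacing = 2,
                          site_charge_pattern = NULL, aspect_ratio = NULL,
                          seed = 1) {
  shape <- match.arg(shape)
  if (is.null(characteristic_size))
    characteristic_size <- switch(shape, sphere = 1.926, rod = 3, needle = 8)
  if (is.null(aspect_ratio))
    aspect_ratio <- switch(shape, sphere = 1, rod = 3, needle = 8)
  if (is.null(site_charge_pattern))
    site_charge_pattern <- switch(shape,
      sphere = list(pos = 0.3, neg = -0.9),
      needle = list(tip = 0.5, body = -0.5, tip_fraction = 1 / 6),
      rod = list(surface = 0.15))
  if (lattice_spacing <= 0) stop("lattice_spacing must be > 0")
  if (characteristic_size <= 0) stop("characteristic_size must be > 0")
  structure(list(shape = shape, characteristic_size = characteristic_size,
                 lattice_spacing = lattice_spacing,
                 site_charge_pattern = site_charge_pattern,
                 aspect_ratio = aspect_ratio, seed = as.integer(seed)),
            class = "ParticleSpec")
}

#' Construct a nanoparticle from explicit sites
#' @param sites data.frame with columns `x`, `y`, `z` \[Angstrom\], `charge`
#'   \[e\] and optionally `label`
#' @param shape shape tag
#' @return object of class `Nanoparticle`
#' @export
new_nanoparticle <- function(sites, shape = "other") {
  stopifnot(all(c("x", "y", "z", "charge") %in% names(sites)))
  if (nrow(sites) < 1) stop("a Nanoparticle needs at least one site")
  if (!all(is.finite(as.matrix(sites[, c("x", "y", "z", "charge")]))))
    stop("site positions and charges must be finite")
  if (is.null(sites$label)) sites$label <- "site"
  rownames(sites) <- NULL
  structure(list(sites = sites, shape = shape), class = "Nanoparticle")
}

#' Total charge of a nanoparticle \[e\]
#' @param p a `Nanoparticle`
#' @return numeric scalar
#' @export
total_charge <- function(p) {
  stopifnot(inherits(p, "Nanoparticle"))
  sum(p$sites$charge)
}

#' Generate an idealized charged nanoparticle
#'
#' @param spec a [particle_spec()]
#' @return a `Nanoparticle` whose sites carry the pattern's region labels
#' @export
make_particle <- function(spec = particle_spec()) {
  stopifnot(inherits(spec, "ParticleSpec"))
  set.seed(spec$seed)
  h <- spec$lattice_spacing
  size_A <- spec$characteristic_size * 10     # nm -> Angstrom
  # cell-centered lattice (sites at half-integer multiples of the spacing):
  # symmetric about the particle center and site-free when the spacing
  # exceeds the particle size
  if (spec$shape == "sphere") {
    R <- size_A / 2
    n <- ceiling(R / h) + 1
    g <- expand.grid(i = seq(-n, n), j = seq(-n, n), k = seq(-n, n))
    pos <- (as.matrix(g) + 0.5) * h
    inside <- sqrt(rowSums(pos^2)) <= R
  } else {
    L <- size_A; W <- size_A / spec$aspect_ratio
    nz <- ceiling(L / 2 / h) + 1
    nxy <- ceiling(W / 2 / h) + 1
    g <- expand.grid(i = seq(-nxy, nxy), j = seq(-nxy, nxy),
                     k = seq(-nz, nz))
    pos <- (as.matrix(g) + 0.5) * h
    inside <- sqrt(pos[, 1]^2 + pos[, 2]^2) <= W / 2 & abs(pos[, 3]) <= L / 2
  }
  if (!any(inside))
    stop("lattice_spacing ", h, " A is too large to place any site in a ",
         spec$shape, " of size ", spec$characteristic_size, " nm")
  g <- g[inside, , drop = FALSE]
  pos <- pos[inside, , drop = FALSE]
  # surface sites = lattice sites missing at least one of the 6 neighbors
  key <- paste(g$i, g$j, g$k)
  have <- new.env(hash = TRUE)
  for (k in key) assign(k, TRUE, envir = have)
  nb <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
              c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  n_nb <- vapply(seq_len(nrow(g)), function(r) {
    sum(vapply(seq_len(6), function(d) {
      exists(paste(g$i[r] + nb[d, 1], g$j[r] + nb[d, 2], g$k[r] + nb[d, 3]),
             envir = have)
    }, logical(1)))
  }, integer(1))
  on_surface <- n_nb < 6L
  pat <- spec$site_charge_pattern
  charge <- rep(0, nrow(g))
  label <- rep("interior", nrow(g))
  if (spec$shape == "sphere") {
    # alternate weak-positive / strong-negative sites along a z-then-
    # azimuth sweep of the surface shell: spatially alternating charges
    # with balanced counts, so the total charge tracks the surface area
    surf_idx <- which(on_surface)
    ord <- surf_idx[order(pos[surf_idx, 3],
                          atan2(pos[surf_idx, 2], pos[surf_idx, 1]))]
    charge[ord] <- rep(c(pat$pos, pat$neg), length.out = length(ord))
    label[ord] <- rep(c("pos", "neg"), length.out = length(ord))
  } else if (spec$shape == "needle") {
    L <- size_A
    tip <- abs(pos[, 3]) >= L / 2 - pat$tip_fraction * L
    charge[on_surface & tip] <- pat$tip
    charge[on_surface & !tip] <- pat$body
    label[on_surface & tip] <- "tip"
    label[on_surface & !tip] <- "body"
  } else {
    charge[on_surface] <- pat$surface
    label[on_surface] <- "surface"
  }
  new_nanoparticle(
    data.frame(x = pos[, 1], y = pos[, 2], z = pos[, 3],
               charge = charge, label = label, stringsAsFactors = FALSE),
    shape = spec$shape)
}

# fixed per-element nonbonded parameters used by the complex fixture
fixture_atom_params <- function(element) {
  tab <- list(N = c(3.30, 0.17, 1.55), C = c(3.60, 0.07, 1.70),
              O = c(3.00, 0.12, 1.52), X = c(3.40, 0.10, 1.70))
  t(vapply(element, function(e) {
    p <- tab[[e]]; if (is.null(p)) p <- tab$X; p
  }, numeric(3)))
}

# side-chain atom layout and charges per residue type (beyond N/CA/C/O/CB).
# Backbone charges are N -0.3, CA +0.1, C +0.5, O -0.5 and CB +0.2, so a
# residue with an uncharged side chain is net neutral; charged side chains
# add exactly +-1 e on their terminal atom.
fixture_sidechain <- function(resname) {
  switch(resname,
    LYS = list(names = c("CG", "NZ"),  el = c("C", "N"),
               d = c(2.8, 4.2), q = c(0, 1)),
    ARG = list(names = c("CG", "NH1"), el = c("C", "N"),
               d = c(2.8, 4.4), q = c(0, 1)),
    GLU = list(names = c("CG", "OE1"), el = c("C", "O"),
               d = c(2.8, 4.0), q = c(0, -1)),
    ASP = list(names = c("OD1"), el = c("O"), d = c(2.9), q = c(-1)),
    GLN = list(names = c("CG", "NE2"), el = c("C", "N"),
               d = c(2.8, 4.0), q = c(0.2, -0.2)),
    SER = list(names = c("OG"), el = c("O"), d = c(2.4), q = c(0)),
    LEU = list(names = c("CG"), el = c("C"), d = c(2.7), q = c(0)),
    NULL)
}

#' Generate a small fully parameterized protein-particle complex
#'
#' A compact ~24-residue helical peptide carrying a lysine/arginine-rich
#' face, plus a mostly negatively charged spherical particle docked against
#' that face at contact distance, with every atom parameterized (charge,
#' Lennard-Jones sigma/epsilon, radius) and a backbone bonded-term list.
#' Used as the standard fixture for the MM/PBSA engine; the opposite-sign
#' contact region guarantees an attractive electrostatic interface.
#'
#' @param seed integer seed
#' @return list with elements `protein` (Structure, chain A), `particle`
#'   (`Nanoparticle`), `params` (`ParameterTable` covering all atoms),
#'   `complex` (Structure, chains A and B), `protein_idx`/`ligand_idx`
#'   (index partition of `complex`), and `terms` (`BondedTerms`)
#' @export
make_complex <- function(seed = 1) {
  set.seed(as.integer(seed))
  # five basic and five acidic residues: the peptide is net neutral, so
  # protein-particle electrostatics vanish in the far-separated limit
  seq_res <- c("SER", "LYS", "GLU", "LEU", "ALA", "LYS", "GLN", "ASP",
               "SER", "LEU", "ARG", "SER", "LYS", "ALA", "GLY", "GLU",
               "ARG", "LEU", "GLN", "ALA", "GLU", "SER", "GLU", "LEU")
  rise <- 1.5; radius <- 2.3; turn <- 100 * pi / 180
  rows <- list()
  for (i in seq_along(seq_res)) {
    ang <- (i - 1) * turn
    ca <- c(radius * cos(ang), radius * sin(ang), (i - 1) * rise)
    out <- c(cos(ang), sin(ang), 0)
    tang <- c(-sin(ang), cos(ang), 0)
    rn <- seq_res[i]
    nm <- c("N", "CA", "C", "O"); el <- c("N", "C", "C", "O")
    q <- c(-0.3, 0.1, 0.5, -0.5)
    xyz <- rbind(ca - 0.9 * tang - c(0, 0, 0.8), ca,
                 ca + 0.9 * tang + c(0, 0, 0.7),
                 ca + 1.2 * tang + 1.0 * out + c(0, 0, 0.9))
    if (rn == "GLY") {
      q[2] <- 0.3                      # keep glycine net-neutral without CB
    } else {
      nm <- c(nm, "CB"); el <- c(el, "C"); q <- c(q, 0.2)
      xyz <- rbind(xyz, ca + 1.5 * out)
      sc <- fixture_sidechain(rn)
      if (!is.null(sc)) {
        nm <- c(nm, sc$names); el <- c(el, sc$el); q <- c(q, sc$q)
        for (s in seq_along(sc$names)) xyz <- rbind(xyz, ca + sc$d[s] * out)
      }
    }
    rows[[i]] <- data.frame(name = nm, element = el, resid = i, resname = rn,
                            chain = "A", x = xyz[, 1], y = xyz[, 2],
                            z = xyz[, 3], charge = q, stringsAsFactors = FALSE)
  }
  a <- do.call(rbind, rows)
  jit <- matrix(rnorm(3 * nrow(a), 0, 0.05), ncol = 3)
  a$x <- a$x + jit[, 1]; a$y <- a$y + jit[, 2]; a$z <- a$z + jit[, 3]
  prm <- fixture_atom_params(a$element)
  a$sigma <- prm[, 1]; a$epsilon <- prm[, 2]; a$radius <- prm[, 3]
  protein <- new_structure(a, metadata = list(fixture = "make_complex",
                                              seed = seed))
  # particle: small mostly-negative sphere docked against the K/R face
  part <- make_particle(particle_spec("sphere", characteristic_size = 1.0,
                                      lattice_spacing = 3,
                                      site_charge_pattern =
                                        list(pos = 0.1, neg = -0.5),
                                      seed = seed))
  # Janus charging for the fixture: the hemisphere facing the protein's
  # acidic face is positive, the far one negative, exactly net-neutral, so
  # the interface is attractive while the whole fixture is charge-free at
  # infinite separation
  surf <- part$sites$label != "interior"
  part$sites$charge <- ifelse(surf & part$sites$x < 0, 0.35,
                              ifelse(surf, -0.35, 0))
  part$sites$charge[surf] <- part$sites$charge[surf] -
    sum(part$sites$charge) / sum(surf)
  part$sites$label <- ifelse(part$sites$charge > 0, "pos",
                             ifelse(part$sites$charge < 0, "neg",
                                    "interior"))
  pxyz <- as.matrix(part$sites[, c("x", "y", "z")])
  mid_z <- mean(a$z)
  rad_ext <- max(sqrt(a$x^2 + a$y^2))
  p_rad <- max(sqrt(rowSums(pxyz^2)))
  center <- c(rad_ext + p_rad + 4.5, 0, mid_z)
  pxyz <- sweep(pxyz, 2, center, "+")
  b <- data.frame(name = "SIT", element = "X",
                  resid = seq_len(nrow(pxyz)), resname = "HAP", chain = "B",
                  x = pxyz[, 1], y = pxyz[, 2], z = pxyz[, 3],
                  charge = part$sites$charge, sigma = 3.4, epsilon = 0.10,
                  radius = 1.70, stringsAsFactors = FALSE)
  cplx <- new_structure(rbind(a, b),
                        metadata = list(fixture = "make_complex", seed = seed))
  params <- data.frame(chain = cplx$atoms$chain, resid = cplx$atoms$resid,
                       atom = cplx$atoms$name, charge = cplx$atoms$charge,
                       sigma = cplx$atoms$sigma, epsilon = cplx$atoms$epsilon,
                       radius = cplx$atoms$radius, stringsAsFactors = FALSE)
  class(params) <- c("ParameterTable", "data.frame")
  # backbone bonds/angles at their fixture geometry (zero strain energy)
  prot_idx <- seq_len(nrow(a))
  bonds <- list(); angles <- list()
  for (i in seq_along(seq_res)) {
    ri <- which(a$resid == i)
    nm <- a$name[ri]
    pair <- function(p, q) c(ri[nm == p], ri[nm == q])
    for (bp in list(c("N", "CA"), c("CA", "C"), c("C", "O"))) {
      ij <- pair(bp[1], bp[2])
      bonds[[length(bonds) + 1L]] <- ij
    }
    if ("CB" %in% nm) bonds[[length(bonds) + 1L]] <- pair("CA", "CB")
    if (i < length(seq_res)) {
      nxt <- which(a$resid == i + 1)
      bonds[[length(bonds) + 1L]] <- c(ri[nm == "C"], nxt[a$name[nxt] == "N"])
    }
    angles[[length(angles) + 1L]] <-
      c(ri[nm == "N"], ri[nm == "CA"], ri[nm == "C"])
  }
  bmat <- do.call(rbind, bonds)
  amat <- do.call(rbind, angles)
  xyzp <- coords(protein)
  r0 <- sqrt(rowSums((xyzp[bmat[, 1], ] - xyzp[bmat[, 2], ])^2))
  th0 <- vapply(seq_len(nrow(amat)), function(r) {
    u <- xyzp[amat[r, 1], ] - xyzp[amat[r, 2], ]
    v <- xyzp[amat[r, 3], ] - xyzp[amat[r, 2], ]
    acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
  }, numeric(1))
  terms <- bonded_terms(
    bonds = data.frame(i = bmat[, 1], j = bmat[, 2], kb = 300, r0 = r0),
    angles = data.frame(i = amat[, 1], j = amat[, 2], k = amat[, 3],
                        ktheta = 50, theta0 = th0))
  list(protein = protein, particle = part, params = params, complex = cplx,
       protein_idx = prot_idx,
       ligand_idx = nrow(a) + seq_len(nrow(b)), terms = terms)
}
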