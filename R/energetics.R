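# Molecular-mechanics energy terms (Coulomb, Lennard-Jones, bonded) and the
# energy model configuration shared by the MM/PBSA engine.

#' Coulomb constant, kcal * Angstrom / (mol * e^2)
#' @export
KCOUL <- 332.0636

# Boltzmann constant in kcal/mol/K
KBOLTZ <- 0.0019872041

#' Energy model configuration
#'
#' All-pairs nonbonded sums (no cutoff), a finite-difference linearized
#' Poisson-Boltzmann polar term and a surface-area nonpolar term. The
#' entropy term `-T*S` is carried in the data model but excluded from
#' totals by default: the reference MM/PBSA tables this package emulates
#' sum exactly the four components vdW + elec + polar + nonpolar.
#'
#' @param solute_dielectric relative dielectric inside atom radii (default 2)
#' @param solvent_dielectric solvent dielectric (default 80)
#' @param ionic_strength monovalent salt \[mM\] (default 150)
#' @param temperature \[K\] (default 300)
#' @param entropy_TS the `T*S` value \[kcal/mol\] if known (default 0)
#' @param include_entropy include `-T*S` in totals (default FALSE)
#' @param pb_grid_spacing finite-difference grid spacing \[Angstrom\]
#'   (default 0.5)
#' @param pb_grid_pad grid margin beyond the solute extent \[Angstrom\]
#'   (default 8)
#' @param pb_stern Stern (ion exclusion) layer beyond atom radii
#'   \[Angstrom\] (default 2)
#' @param pb_tol relative residual tolerance of the PB solver (default 1e-6)
#' @param pb_maxit iteration budget of the PB solver (default 3000)
#' @param sasa_probe solvent probe radius \[Angstrom\] (default 1.4)
#' @param sasa_points sphere sample points per atom (default 960)
#' @param sasa_gamma surface-tension coefficient \[kcal/(mol Angstrom^2)\]
#'   (default 0.00542)
#' @param sasa_offset additive nonpolar constant \[kcal/mol\] (default 0.92)
#' @return object of class `EnergyModelConfig`
#' @export
energy_config <- function(solute_dielectric = 2, solvent_dielectric = 80,
                          ionic_strength = 150, temperature = 300,
                          entropy_TS = 0, include_entropy = FALSE,
                          pb_grid_spacing = 0.5, pb_grid_pad = 8,
                          pb_stern = 2, pb_tol = 1e-6, pb_maxit = 3000,
                          sasa_probe = 1.4, sasa_points = 960,
                          sasa_gamma = 0.00542, sasa_offset = 0.92) {
  if (solute_dielectric <= 0 || solvent_dielectric <= 0)
    stop("dielectrics must be > 0")
  if (pb_grid_spacing <= 0) stop("pb_grid_spacing must be > 0")
  if (temperature <= 0) stop("temperature must be > 0")
  structure(list(coulomb_constant = KCOUL,
                 solute_dielectric = solute_dielectric,
                 solvent_dielectric = solvent_dielectric,
                 ionic_strength = ionic_strength, temperature = temperature,
                 entropy_TS = entropy_TS, include_entropy = include_entropy,
                 pb_grid_spacing = pb_grid_spacing, pb_grid_pad = pb_grid_pad,
                 pb_stern = pb_stern, pb_tol = pb_tol, pb_maxit = pb_maxit,
                 sasa_probe = sasa_probe, sasa_points = sasa_points,
                 sasa_gamma = sasa_gamma, sasa_offset = sasa_offset),
            class = "EnergyModelConfig")
}

check_charged <- function(s, idx) {
  q <- s$atoms$charge[idx]
  if (anyNA(q)) {
    bad <- idx[which(is.na(q))[1]]
    stop("atom ", bad, " (", s$atoms$chain[bad], ":", s$atoms$resid[bad],
         ":", s$atoms$name[bad], ") has no charge")
  }
  q
}

resolve_group <- function(s, group) {
  if (is.null(group)) seq_len(n_atoms(s))
  else if (inherits(group, "SelectionSpec")) apply_selection(s, group)
  else as.integer(group)
}

cross_dist <- function(xa, xb) {
  # |xa_i - xb_j| matrix
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

# pairwise Coulomb energy matrix between two disjoint atom groups; when
# the groups are identical the diagonal is zeroed (self-pairs excluded)
coulomb_pair_matrix <- function(s, cfg, ia, ib) {
  internal <- identical(ia, ib)
  qa <- check_charged(s, ia); qb <- check_charged(s, ib)
  xyz <- coords(s)
  d <- cross_dist(xyz[ia, , drop = FALSE], xyz[ib, , drop = FALSE])
  if (internal) diag(d) <- Inf
  if (any(d == 0)) stop("coincident atoms (zero distance) in Coulomb sum")
  cfg$coulomb_constant * outer(qa, qb) / (cfg$solute_dielectric * d)
}

lj_pair_matrix <- function(s, cfg, ia, ib) {
  internal <- identical(ia, ib)
  a <- s$atoms
  for (col in c("sigma", "epsilon"))
    if (anyNA(a[[col]][c(ia, ib)]))
      stop("missing Lennard-Jones ", col, " for atom(s) ",
           paste(head(c(ia, ib)[is.na(a[[col]][c(ia, ib)])], 3),
                 collapse = ", "))
  xyz <- coords(s)
  d <- cross_dist(xyz[ia, , drop = FALSE], xyz[ib, , drop = FALSE])
  if (internal) diag(d) <- Inf
  if (any(d == 0)) stop("coincident atoms (zero distance) in LJ sum")
  sig <- outer(a$sigma[ia], a$sigma[ib], "+") / 2     # Lorentz
  eps <- sqrt(outer(a$epsilon[ia], a$epsilon[ib]))    # Berthelot
  sr6 <- (sig / d)^6
  4 * eps * (sr6^2 - sr6)
}

pair_energy_total <- function(s, cfg, group_a, group_b, matfun) {
  ia <- resolve_group(s, group_a)
  ib <- resolve_group(s, group_b)
  if (setequal(ia, ib)) {
    m <- matfun(s, cfg, ia, ia)
    sum(m[upper.tri(m)])                     # unique internal pairs
  } else {
    if (length(intersect(ia, ib)) > 0)
      stop("groups overlap; use identical groups for an internal sum or ",
           "disjoint groups for a cross sum")
    sum(matfun(s, cfg, ia, ib))
  }
}

#' Coulomb electrostatic energy
#'
#' `sum k_C q_i q_j / (eps_solute r_ij)` over unique internal pairs (when
#' the groups coincide or are omitted) or over cross pairs of two disjoint
#' groups. No distance cutoff.
#'
#' @param s a `Structure` with charges on every involved atom
#' @param cfg an [energy_config()]
#' @param group_a,group_b atom index vectors or `SelectionSpec`s; both
#'   `NULL` (default) sums over all unique pairs
#' @return energy \[kcal/mol\]
#' @export
coulomb_energy <- function(s, cfg = energy_config(), group_a = NULL,
                           group_b = NULL) {
  pair_energy_total(s, cfg, group_a, group_b, coulomb_pair_matrix)
}

#' Lennard-Jones energy
#'
#' `sum 4 eps [(sig/r)^12 - (sig/r)^6]` with Lorentz-Berthelot combining
#' (arithmetic-mean sigma, geometric-mean epsilon); grouping as in
#' [coulomb_energy()].
#'
#' @inheritParams coulomb_energy
#' @return energy \[kcal/mol\]
#' @export
lj_energy <- function(s, cfg = energy_config(), group_a = NULL,
                      group_b = NULL) {
  pair_energy_total(s, cfg, group_a, group_b, lj_pair_matrix)
}

#' Bonded-term list
#'
#' @param bonds data.frame `i`, `j`, `kb` \[kcal/mol/A^2\], `r0` \[A\];
#'   energy `kb (r - r0)^2`
#' @param angles data.frame `i`, `j`, `k`, `ktheta` \[kcal/mol/rad^2\],
#'   `theta0` \[degrees\]; energy `ktheta (theta - theta0)^2`
#' @param dihedrals data.frame `i`, `j`, `k`, `l`, `kphi` \[kcal/mol\],
#'   `n` (periodicity), `delta` \[degrees\]; energy
#'   `kphi (1 + cos(n phi - delta))`. Impropers use the same form.
#' @return object of class `BondedTerms`
#' @export
bonded_terms <- function(bonds = NULL, angles = NULL, dihedrals = NULL) {
  empty <- function(cols) as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
  if (is.null(bonds)) bonds <- empty(c("i", "j", "kb", "r0"))
  if (is.null(angles)) angles <- empty(c("i", "j", "k", "ktheta", "theta0"))
  if (is.null(dihedrals))
    dihedrals <- empty(c("i", "j", "k", "l", "kphi", "n", "delta"))
  if (any(bonds$kb < 0) || any(angles$ktheta < 0))
    stop("force constants must be >= 0")
  structure(list(bonds = bonds, angles = angles, dihedrals = dihedrals),
            class = "BondedTerms")
}

dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  if (sum(n1^2) == 0 || sum(n2^2) == 0)
    stop("undefined dihedral: collinear or coincident atoms")
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1])
  b2n <- sqrt(sum(b2^2))
  atan2(sum(m1 * n2) / b2n, sum(n1 * n2))
}

#' Bonded (bond + angle + dihedral/improper) energy
#'
#' Harmonic bonds `kb (r - r0)^2`, harmonic angles `ktheta (theta -
#' theta0)^2` and periodic dihedrals `kphi (1 + cos(n phi - delta))`.
#'
#' @param s a `Structure`
#' @param terms a [bonded_terms()] list with valid atom indices
#' @return energy \[kcal/mol\]
#' @export
bonded_energy <- function(s, terms) {
  stopifnot(inherits(s, "Structure"), inherits(terms, "BondedTerms"))
  xyz <- coords(s)
  n <- nrow(xyz)
  idx_all <- c(terms$bonds$i, terms$bonds$j, terms$angles$i, terms$angles$j,
               terms$angles$k, terms$dihedrals$i, terms$dihedrals$j,
               terms$dihedrals$k, terms$dihedrals$l)
  if (length(idx_all) > 0 && (min(idx_all) < 1 || max(idx_all) > n))
    stop("bonded term references an atom index outside the structure")
  e <- 0
  b <- terms$bonds
  if (nrow(b) > 0) {
    r <- sqrt(rowSums((xyz[b$i, , drop = FALSE] - xyz[b$j, , drop = FALSE])^2))
    e <- e + sum(b$kb * (r - b$r0)^2)
  }
  an <- terms$angles
  if (nrow(an) > 0) {
    th <- vapply(seq_len(nrow(an)), function(r) {
      u <- xyz[an$i[r], ] - xyz[an$j[r], ]
      v <- xyz[an$k[r], ] - xyz[an$j[r], ]
      nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
      if (nu == 0 || nv == 0) stop("undefined angle: coincident atoms")
      acos(pmin(1, pmax(-1, sum(u * v) / (nu * nv))))
    }, numeric(1))
    e <- e + sum(an$ktheta * (th - an$theta0 * pi / 180)^2)
  }
  dh <- terms$dihedrals
  if (nrow(dh) > 0) {
    phi <- vapply(seq_len(nrow(dh)), function(r) {
      dihedral_angle(xyz[dh$i[r], ], xyz[dh$j[r], ], xyz[dh$k[r], ],
                     xyz[dh$l[r], ])
    }, numeric(1))
    e <- e + sum(dh$kphi * (1 + cos(dh$n * phi - dh$delta * pi / 180)))
  }
  e
}
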