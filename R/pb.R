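# Finite-difference linearized Poisson-Boltzmann solver.
#
# The potential phi is carried in kcal/mol/e. On a cubic grid the
# discretized equation at each interior node reads
#   sum_faces eps_face (phi - phi_nb) + eps_out kappa^2 h^2 [ion] phi
#     = 4 pi k_C q_node / h,
# with eps_face the harmonic mean of the node dielectrics (solute value
# inside atom radii, solvent outside), the Debye term active only outside
# the Stern layer, charges spread to the 8 surrounding nodes trilinearly,
# and Debye-Hueckel Dirichlet values on the box faces. The reaction-field
# (polar solvation) energy is (1/2) sum q_i [phi_solvated - phi_uniform]
# evaluated at the atom centers; solving the uniform-dielectric reference
# on the same grid with the same charge spreading cancels the grid
# self-energy exactly.

# Jacobi-preconditioned conjugate gradient for a sparse SPD system
cg_solve <- function(A, b, x0, tol, maxit) {
  dinv <- 1 / Matrix::diag(A)
  x <- x0
  r <- b - as.numeric(A %*% x)
  z <- dinv * r
  p <- z
  rz <- sum(r * z)
  bnorm <- sqrt(sum(b^2))
  if (bnorm == 0) return(list(x = 0 * x, iters = 0L, rel = 0))
  for (it in seq_len(maxit)) {
    Ap <- as.numeric(A %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    rel <- sqrt(sum(r^2)) / bnorm
    if (rel < tol) return(list(x = x, iters = it, rel = rel))
    z <- dinv * r
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  stop("PB solver did not converge in ", maxit,
       " iterations (relative residual ", signif(rel, 3), ")")
}

# trilinear spreading of point charges onto grid nodes
spread_charges <- function(xyz, q, ax) {
  nx <- length(ax$x); ny <- length(ax$y); nz <- length(ax$z)
  qn <- numeric(nx * ny * nz)
  h <- ax$h
  fx <- (xyz[, 1] - ax$x[1]) / h
  fy <- (xyz[, 2] - ax$y[1]) / h
  fz <- (xyz[, 3] - ax$z[1]) / h
  i0 <- floor(fx); j0 <- floor(fy); k0 <- floor(fz)
  if (any(i0 < 0) || any(i0 >= nx - 1) || any(j0 < 0) || any(j0 >= ny - 1) ||
      any(k0 < 0) || any(k0 >= nz - 1))
    stop("atom outside the PB grid; increase pb_grid_pad")
  wx <- fx - i0; wy <- fy - j0; wz <- fz - k0
  for (a in seq_along(q)) {
    if (q[a] == 0) next
    for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
      w <- (if (di) wx[a] else 1 - wx[a]) *
           (if (dj) wy[a] else 1 - wy[a]) *
           (if (dk) wz[a] else 1 - wz[a])
      node <- (i0[a] + di) + (j0[a] + dj) * nx + (k0[a] + dk) * nx * ny + 1
      qn[node] <- qn[node] + w * q[a]
    }
  }
  qn
}

# trilinear interpolation of a node field at atom positions
interp_field <- function(phi, xyz, ax) {
  nx <- length(ax$x); ny <- length(ax$y)
  h <- ax$h
  fx <- (xyz[, 1] - ax$x[1]) / h
  fy <- (xyz[, 2] - ax$y[1]) / h
  fz <- (xyz[, 3] - ax$z[1]) / h
  i0 <- floor(fx); j0 <- floor(fy); k0 <- floor(fz)
  wx <- fx - i0; wy <- fy - j0; wz <- fz - k0
  out <- numeric(nrow(xyz))
  for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
    w <- (if (di) wx else 1 - wx) * (if (dj) wy else 1 - wy) *
         (if (dk) wz else 1 - wz)
    node <- (i0 + di) + (j0 + dj) * length(ax$x) +
            (k0 + dk) * nx * ny + 1
    out <- out + w * phi[node]
  }
  out
}

# mark grid nodes within distance `extra` of any atom sphere
nodes_inside <- function(ax, xyz, radii, extra = 0) {
  nx <- length(ax$x); ny <- length(ax$y); nz <- length(ax$z)
  inside <- logical(nx * ny * nz)
  for (a in seq_len(nrow(xyz))) {
    r <- radii[a] + extra
    ix <- which(abs(ax$x - xyz[a, 1]) <= r)
    iy <- which(abs(ax$y - xyz[a, 2]) <= r)
    iz <- which(abs(ax$z - xyz[a, 3]) <= r)
    if (!length(ix) || !length(iy) || !length(iz)) next
    g <- expand.grid(ix = ix, iy = iy, iz = iz)
    d2 <- (ax$x[g$ix] - xyz[a, 1])^2 + (ax$y[g$iy] - xyz[a, 2])^2 +
          (ax$z[g$iz] - xyz[a, 3])^2
    hit <- d2 <= r^2
    inside[(g$ix[hit] - 1) + (g$iy[hit] - 1) * nx +
           (g$iz[hit] - 1) * nx * ny + 1] <- TRUE
  }
  inside
}

# one finite-difference solve; eps is the node dielectric vector,
# ion_diag the per-node Debye diagonal term, phib the Dirichlet value at
# every node (used on the boundary only), qn the node charges.
fd_solve <- function(ax, eps, ion_diag, phib, qn, cfg) {
  nx <- length(ax$x); ny <- length(ax$y); nz <- length(ax$z)
  ntot <- nx * ny * nz
  h <- ax$h
  ii <- rep(seq_len(nx), times = ny * nz)
  jj <- rep(rep(seq_len(ny), each = nx), times = nz)
  kk <- rep(seq_len(nz), each = nx * ny)
  interior <- ii > 1 & ii < nx & jj > 1 & jj < ny & kk > 1 & kk < nz
  unk <- integer(ntot); unk[interior] <- seq_len(sum(interior))
  nunk <- sum(interior)
  diag_v <- ion_diag[interior] * h^2
  rhs <- 4 * pi * cfg$coulomb_constant * qn[interior] / h
  trip_i <- integer(0); trip_j <- integer(0); trip_x <- numeric(0)
  for (dir in 1:3) {
    off <- c(1L, nx, nx * ny)[dir]
    p <- seq_len(ntot - off)
    # exclude pairs that wrap around an axis
    ok <- switch(dir, ii[p] < nx, jj[p] < ny, kk[p] < nz)
    p <- p[ok]
    pn <- p + off
    w <- 2 * eps[p] * eps[pn] / (eps[p] + eps[pn])
    bi <- interior[p]; bn <- interior[pn]
    both <- bi & bn
    if (any(both)) {
      u1 <- unk[p[both]]; u2 <- unk[pn[both]]; ww <- w[both]
      trip_i <- c(trip_i, u1, u2); trip_j <- c(trip_j, u2, u1)
      trip_x <- c(trip_x, -ww, -ww)
    }
    # diagonal and boundary contributions, accumulated per endpoint
    dvec <- numeric(nunk)
    if (any(bi)) {
      add <- rowsum(w[bi], unk[p[bi]])
      dvec[as.integer(rownames(add))] <- dvec[as.integer(rownames(add))] + add
    }
    if (any(bn)) {
      add <- rowsum(w[bn], unk[pn[bn]])
      dvec[as.integer(rownames(add))] <- dvec[as.integer(rownames(add))] + add
    }
    diag_v <- diag_v + dvec
    b1 <- bi & !bn
    if (any(b1)) {
      rh <- rowsum(w[b1] * phib[pn[b1]], unk[p[b1]])
      rhs[as.integer(rownames(rh))] <- rhs[as.integer(rownames(rh))] + rh
    }
    b2 <- bn & !bi
    if (any(b2)) {
      rh <- rowsum(w[b2] * phib[p[b2]], unk[pn[b2]])
      rhs[as.integer(rownames(rh))] <- rhs[as.integer(rownames(rh))] + rh
    }
  }
  A <- Matrix::sparseMatrix(i = c(seq_len(nunk), trip_i),
                            j = c(seq_len(nunk), trip_j),
                            x = c(diag_v, trip_x),
                            dims = c(nunk, nunk))
  sol <- cg_solve(A, rhs, x0 = phib[interior], tol = cfg$pb_tol,
                  maxit = cfg$pb_maxit)
  phi <- phib                      # boundary keeps its Dirichlet value
  phi[interior] <- sol$x
  phi
}

#' Polar solvation energy by finite-difference linearized Poisson-Boltzmann
#'
#' Solves the linearized PB equation on a cubic grid (dielectric map:
#' `solute_dielectric` inside atom radii, `solvent_dielectric` outside;
#' Debye screening from `ionic_strength` outside the Stern layer;
#' Debye-Hueckel boundary values), then subtracts a uniform
#' `solute_dielectric` reference solved on the identical grid. The result
#' is the reaction-field energy `G_polar = 1/2 sum q_i (phi_solv -
#' phi_ref)(r_i)`.
#'
#' @param s a `Structure` with charges and radii on all atoms
#' @param cfg an [energy_config()]
#' @param per_atom return the per-atom reaction-field contributions too
#' @return energy \[kcal/mol\], or a list `(G_polar, per_atom)` when
#'   `per_atom = TRUE`
#' @export
pb_polar_energy <- function(s, cfg = energy_config(), per_atom = FALSE) {
  stopifnot(inherits(s, "Structure"))
  a <- s$atoms
  if (anyNA(a$radius))
    stop("missing radius for atom(s) ",
         paste(head(which(is.na(a$radius)), 3), collapse = ", "))
  q <- check_charged(s, seq_len(nrow(a)))
  if (all(q == 0)) {
    if (per_atom) return(list(G_polar = 0, per_atom = numeric(nrow(a))))
    return(0)
  }
  xyz <- coords(s)
  h <- cfg$pb_grid_spacing
  pad <- cfg$pb_grid_pad + max(a$radius)
  lo <- apply(xyz, 2, min) - pad
  hi <- apply(xyz, 2, max) + pad
  mk_axis <- function(l, u) {
    n <- ceiling((u - l) / h) + 1
    mid <- (l + u) / 2
    mid + (seq_len(n) - (n + 1) / 2) * h
  }
  ax <- list(x = mk_axis(lo[1], hi[1]), y = mk_axis(lo[2], hi[2]),
             z = mk_axis(lo[3], hi[3]), h = h)
  nx <- length(ax$x); ny <- length(ax$y); nz <- length(ax$z)
  ntot <- nx * ny * nz
  gx <- rep(ax$x, times = ny * nz)
  gy <- rep(rep(ax$y, each = nx), times = nz)
  gz <- rep(ax$z, each = nx * ny)
  inside <- nodes_inside(ax, xyz, a$radius)
  eps_solv <- ifelse(inside, cfg$solute_dielectric, cfg$solvent_dielectric)
  # Debye parameter: eps_out * kappa^2 = 8 pi k_C n0 / (k_B T), n0 in e/A^3
  n0 <- cfg$ionic_strength * 6.02214076e-7
  kT <- KBOLTZ * cfg$temperature
  eps_kappa2 <- 8 * pi * cfg$coulomb_constant * n0 / kT
  ion_ok <- !nodes_inside(ax, xyz, a$radius, extra = cfg$pb_stern)
  ion_diag <- ifelse(ion_ok, eps_kappa2, 0)
  kappa <- sqrt(eps_kappa2 / cfg$solvent_dielectric)
  qn <- spread_charges(xyz, q, ax)
  # Dirichlet guesses/boundary values at every node
  charged <- which(q != 0)
  dh_field <- function(epsv, kap) {
    out <- numeric(ntot)
    for (ai in charged) {
      d <- sqrt((gx - xyz[ai, 1])^2 + (gy - xyz[ai, 2])^2 +
                (gz - xyz[ai, 3])^2)
      d[d < h / 2] <- h / 2
      out <- out + cfg$coulomb_constant * q[ai] * exp(-kap * d) / (epsv * d)
    }
    out
  }
  phib_solv <- dh_field(cfg$solvent_dielectric, kappa)
  phib_ref <- dh_field(cfg$solute_dielectric, 0)
  phi_solv <- fd_solve(ax, eps_solv, ion_diag, phib_solv, qn, cfg)
  eps_ref <- rep(cfg$solute_dielectric, ntot)
  phi_ref <- fd_solve(ax, eps_ref, numeric(ntot), phib_ref, qn, cfg)
  dphi <- interp_field(phi_solv - phi_ref, xyz, ax)
  contrib <- 0.5 * q * dphi
  if (per_atom) list(G_polar = sum(contrib), per_atom = contrib)
  else sum(contrib)
}
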