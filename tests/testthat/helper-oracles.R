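# Independent brute-force oracles used to cross-check the package
# implementations. These deliberately share no code with the package
# internals: superposition uses Horn's quaternion method instead of SVD,
# energy sums are plain double loops, clustering is a literal re-read of
# the neighbor-count algorithm.

# random toy structure with full parameters
random_structure <- function(n, seed = 1, spread = 8) {
  set.seed(seed)
  new_structure(data.frame(
    name = paste0("X", seq_len(n)), element = "C",
    resid = seq_len(n), resname = "UNK", chain = "A",
    x = runif(n, -spread, spread), y = runif(n, -spread, spread),
    z = runif(n, -spread, spread),
    charge = round(runif(n, -1, 1), 3),
    sigma = runif(n, 2.5, 4), epsilon = runif(n, 0.05, 0.3),
    radius = runif(n, 1.2, 2), stringsAsFactors = FALSE))
}

# optimal-superposition RMSD via Horn's closed-form quaternion method
quaternion_rmsd <- function(xa, xb) {
  stopifnot(nrow(xa) == nrow(xb))
  n <- nrow(xa)
  ca <- scale(xa, scale = FALSE)
  cb <- scale(xb, scale = FALSE)
  M <- t(ca) %*% cb
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,       -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(ca^2) + sum(cb^2) - 2 * lam) / n
  sqrt(max(0, msd))
}

# plain double-loop Coulomb over unique pairs / cross pairs
brute_coulomb <- function(s, eps = 1, ia = NULL, ib = NULL) {
  a <- s$atoms
  if (is.null(ia)) ia <- seq_len(nrow(a))
  e <- 0
  if (is.null(ib)) {
    for (p in seq_along(ia)) for (q in seq_along(ia)) {
      if (q <= p) next
      i <- ia[p]; j <- ia[q]
      r <- sqrt((a$x[i] - a$x[j])^2 + (a$y[i] - a$y[j])^2 +
                (a$z[i] - a$z[j])^2)
      e <- e + 332.0636 * a$charge[i] * a$charge[j] / (eps * r)
    }
  } else {
    for (i in ia) for (j in ib) {
      r <- sqrt((a$x[i] - a$x[j])^2 + (a$y[i] - a$y[j])^2 +
                (a$z[i] - a$z[j])^2)
      e <- e + 332.0636 * a$charge[i] * a$charge[j] / (eps * r)
    }
  }
  e
}

brute_lj <- function(s, ia = NULL, ib = NULL) {
  a <- s$atoms
  if (is.null(ia)) ia <- seq_len(nrow(a))
  pair_e <- function(i, j) {
    r <- sqrt((a$x[i] - a$x[j])^2 + (a$y[i] - a$y[j])^2 +
              (a$z[i] - a$z[j])^2)
    sg <- (a$sigma[i] + a$sigma[j]) / 2
    ep <- sqrt(a$epsilon[i] * a$epsilon[j])
    4 * ep * ((sg / r)^12 - (sg / r)^6)
  }
  e <- 0
  if (is.null(ib)) {
    for (p in seq_along(ia)) for (q in seq_along(ia))
      if (q > p) e <- e + pair_e(ia[p], ia[q])
  } else {
    for (i in ia) for (j in ib) e <- e + pair_e(i, j)
  }
  e
}

# literal per-pair time variance of internal distances
brute_dfmat <- function(traj, idx) {
  nf <- n_frames(traj)
  na <- length(idx)
  tau <- matrix(0, na, na)
  for (p in seq_len(na)) for (q in seq_len(na)) {
    if (p == q) next
    d <- numeric(nf)
    for (f in seq_len(nf)) {
      fr <- coords(get_frame(traj, f))
      d[f] <- sqrt(sum((fr[idx[p], ] - fr[idx[q], ])^2))
    }
    tau[p, q] <- mean(d^2) - mean(d)^2
  }
  tau
}

# literal GROMOS neighbor counting on a precomputed RMSD matrix
brute_gromos <- function(m, cutoff) {
  nf <- nrow(m)
  remaining <- rep(TRUE, nf)
  labels <- integer(nf)
  cl <- 0
  while (any(remaining)) {
    best <- -1; center <- NA
    for (i in seq_len(nf)) {
      if (!remaining[i]) next
      cnt <- sum(m[remaining, i] <= cutoff)
      if (cnt > best) { best <- cnt; center <- i }
    }
    members <- which(remaining & m[, center] <= cutoff)
    cl <- cl + 1
    labels[members] <- cl
    remaining[members] <- FALSE
  }
  sizes <- tabulate(labels, cl)
  ord <- order(-sizes, seq_len(cl))
  relab <- integer(cl); relab[ord] <- seq_len(cl)
  relab[labels]
}

# numerical Hessian of the pairwise harmonic network energy
fd_hessian <- function(model, h = 1e-4) {
  x0 <- as.vector(t(model$nodes))
  n <- length(x0)
  E <- function(x) enm_energy(model, matrix(x, ncol = 3, byrow = TRUE))
  H <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in i:n) {
    ei <- ej <- numeric(n); ei[i] <- h; ej[j] <- h
    val <- (E(x0 + ei + ej) - E(x0 + ei - ej) -
            E(x0 - ei + ej) + E(x0 - ei - ej)) / (4 * h^2)
    H[i, j] <- val; H[j, i] <- val
  }
  H
}

# random rigid motion of a structure
rigid_move <- function(s, seed = 1) {
  set.seed(seed)
  th <- runif(3, 0, 2 * pi)
  Rx <- matrix(c(1, 0, 0, 0, cos(th[1]), -sin(th[1]),
                 0, sin(th[1]), cos(th[1])), 3, 3, byrow = TRUE)
  Ry <- matrix(c(cos(th[2]), 0, sin(th[2]), 0, 1, 0,
                 -sin(th[2]), 0, cos(th[2])), 3, 3, byrow = TRUE)
  Rz <- matrix(c(cos(th[3]), -sin(th[3]), 0, sin(th[3]), cos(th[3]), 0,
                 0, 0, 1), 3, 3, byrow = TRUE)
  tr <- runif(3, -15, 15)
  set_coords(s, sweep(coords(s) %*% t(Rx %*% Ry %*% Rz), 2, tr, "+"))
}
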