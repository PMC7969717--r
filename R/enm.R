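# Anisotropic elastic-network model (ANM) on C-alpha nodes: harmonic
# springs between nodes within a distance cutoff, Hessian eigenmodes as the
# low-frequency collective motions.

#' Build an anisotropic elastic-network model
#'
#' Nodes are the C-alpha atoms; every node pair within `cutoff` is joined by
#' a harmonic spring of uniform constant `k` acting on the pair distance.
#' The 3N x 3N Hessian has off-diagonal 3x3 super-blocks
#' `-k (dr dr^T) / |dr|^2` for connected pairs and diagonal blocks equal to
#' the negative sum of the row's off-diagonal blocks, which makes rigid
#' translations and rotations exact zero modes.
#'
#' @param s a `Structure` with C-alpha atoms (or any structure with
#'   `sel = selection_spec("all")` to use every atom as a node)
#' @param cutoff spring distance cutoff \[Angstrom\], default 15
#' @param k uniform spring constant (arbitrary units; mode shapes are
#'   independent of it), default 1
#' @param sel node selection, default C-alpha
#' @return object of class `ENMModel`: `nodes` (N x 3), `hessian`
#'   (3N x 3N), `cutoff`, `spring_constant`, `node_idx`
#' @export
build_enm <- function(s, cutoff = 15, k = 1, sel = selection_spec("calpha")) {
  stopifnot(inherits(s, "Structure"))
  idx <- apply_selection(s, sel)
  nodes <- coords(s)[idx, , drop = FALSE]
  n <- nrow(nodes)
  if (n < 2) stop("elastic network needs at least 2 nodes")
  sv <- svd(scale(nodes, scale = FALSE))$d
  if (n >= 3 && sv[2] < 1e-8 * max(sv[1], 1))
    stop("nodes are collinear; the elastic network is degenerate")
  H <- matrix(0, 3 * n, 3 * n)
  d <- as.matrix(dist(nodes))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (d[i, j] > cutoff || d[i, j] == 0) next
      dr <- nodes[j, ] - nodes[i, ]
      blk <- k * (dr %o% dr) / sum(dr^2)
      bi <- (3 * i - 2):(3 * i); bj <- (3 * j - 2):(3 * j)
      H[bi, bj] <- H[bi, bj] - blk
      H[bj, bi] <- H[bj, bi] - blk
      H[bi, bi] <- H[bi, bi] + blk
      H[bj, bj] <- H[bj, bj] + blk
    }
  }
  structure(list(nodes = nodes, hessian = H, cutoff = cutoff,
                 spring_constant = k, node_idx = idx),
            class = "ENMModel")
}

#' Elastic-network potential energy of a deformed geometry
#'
#' `V = (k/2) * sum over connected pairs (d_ij - d_ij^0)^2`; zero for any
#' rigid transformation of the reference nodes. Mainly used for validating
#' the Hessian against numerical differentiation.
#'
#' @param model an `ENMModel`
#' @param nodes N x 3 deformed node coordinates
#' @return potential energy (spring-constant units x Angstrom^2)
#' @export
enm_energy <- function(model, nodes) {
  d0 <- as.matrix(dist(model$nodes))
  d <- as.matrix(dist(nodes))
  con <- d0 <= model$cutoff & d0 > 0
  0.5 * model$spring_constant * sum(((d - d0)[con])^2) / 2  # pairs counted twice
}

#' Low-frequency normal modes of an elastic network
#'
#' Diagonalizes the Hessian, discards the 6 rigid-body modes (identified by
#' eigenvalue below `1e-8` times the largest eigenvalue; exactly 6 must fall
#' below the threshold or an error is raised), and returns the `n_modes`
#' lowest non-trivial modes.
#'
#' @param model an `ENMModel`
#' @param n_modes number of non-trivial modes to return (default 5)
#' @return object of class `ModeSet`: `eigenvalues` (ascending),
#'   `eigenvectors` (3N x n_modes, orthonormal columns), `n_trivial`,
#'   `all_eigenvalues`
#' @export
compute_modes <- function(model, n_modes = 5) {
  stopifnot(inherits(model, "ENMModel"))
  eig <- eigen(model$hessian, symmetric = TRUE)
  ev <- rev(eig$values)                       # ascending
  vec <- eig$vectors[, rev(seq_along(ev)), drop = FALSE]
  thr <- 1e-8 * max(ev)
  n_triv <- sum(ev < thr)
  if (n_triv != 6)
    stop("expected exactly 6 rigid-body modes, found ", n_triv,
         " eigenvalues below threshold; the network may be disconnected ",
         "or degenerate")
  avail <- length(ev) - n_triv
  if (n_modes > avail)
    stop("requested ", n_modes, " modes but only ", avail, " are available")
  keep <- (n_triv + 1):(n_triv + n_modes)
  structure(list(eigenvalues = ev[keep],
                 eigenvectors = vec[, keep, drop = FALSE],
                 n_trivial = n_triv, all_eigenvalues = ev),
            class = "ModeSet")
}

#' Per-node displacement magnitudes of one mode
#' @param modes a `ModeSet`
#' @param mode mode index (1 = lowest non-trivial)
#' @return numeric vector of per-node displacement norms
#' @export
mode_amplitudes <- function(modes, mode = 1) {
  v <- modes$eigenvectors[, mode]
  sqrt(colSums(matrix(v, nrow = 3)^2))
}

#' Overlap of normal modes with the open-to-locked transition
#'
#' The absolute cosine between each eigenvector and the normalized
#' difference vector `v2 - v1` of the reference pair (on the pair's
#' selection, which must match the model's node set).
#'
#' @param modes a `ModeSet`
#' @param refs a `ReferencePair`
#' @return numeric vector of per-mode overlaps in \[0, 1\]
#' @export
mode_overlap <- function(modes, refs) {
  stopifnot(inherits(modes, "ModeSet"), inherits(refs, "ReferencePair"))
  idx <- apply_selection(refs$v1, refs$selection)
  dv <- coord_vector(refs$v2_aligned, idx) - coord_vector(refs$v1, idx)
  if (length(dv) != nrow(modes$eigenvectors))
    stop("mode dimension (", nrow(modes$eigenvectors),
         ") does not match the reference selection (", length(dv), ")")
  dv <- dv / sqrt(sum(dv^2))
  as.numeric(abs(t(modes$eigenvectors) %*% dv))
}
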