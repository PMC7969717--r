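# Conformational analysis: least-squares superposition, the open/locked
# transition coordinate lambda, distance-fluctuation matrices and
# RMSD-criterion (GROMOS-style) trajectory clustering.

check_superposable <- function(xyz) {
  if (nrow(xyz) < 3) stop("superposition needs at least 3 selected atoms")
  sv <- svd(scale(xyz, scale = FALSE))$d
  if (sv[2] < 1e-8 * max(sv[1], 1))
    stop("selected atoms are collinear; superposition is underdetermined")
}

#' Least-squares superposition of one structure onto another
#'
#' The optimal proper rotation + translation minimizing the coordinate RMSD
#' on the selection is found (Kabsch, via [bio3d::fit.xyz()]) and applied to
#' all atoms of `mobile`.
#'
#' @param mobile,target `Structure`s sharing the atom list on `sel`
#' @param sel a `SelectionSpec` (default: all atoms)
#' @return list with `structure` (the transformed `mobile`) and `rmsd`
#'   \[Angstrom\] on the selection
#' @export
superpose <- function(mobile, target, sel = NULL) {
  stopifnot(inherits(mobile, "Structure"), inherits(target, "Structure"))
  idx <- apply_selection(target, sel)
  idx_m <- apply_selection(mobile, sel)
  if (length(idx) != length(idx_m))
    stop("selection sizes differ between mobile and target")
  check_superposable(coords(target)[idx, , drop = FALSE])
  ci <- bio3d::atom2xyz(idx)
  fitted <- bio3d::fit.xyz(fixed = coord_vector(target),
                           mobile = coord_vector(mobile),
                           fixed.inds = ci, mobile.inds = ci)
  fitted <- as.numeric(fitted)
  d <- fitted[ci] - coord_vector(target)[ci]
  rmsd <- sqrt(sum(d^2) / length(idx))
  list(structure = set_coords(mobile, fitted), rmsd = rmsd)
}

#' Construct an open/locked reference pair
#'
#' The two references define the axis of the transition coordinate lambda.
#' On construction the locked reference is canonically superposed onto the
#' open one on the selection (`v2_aligned`); the lambda axis is defined
#' between `v1` and `v2_aligned`, so that lambda is exactly 0 at the open
#' and 1 at the locked reference regardless of how the input structures were
#' oriented. The original `v2` is kept untouched.
#'
#' @param v1 open-state `Structure` (lambda = 0)
#' @param v2 locked-state `Structure` (lambda = 1)
#' @param selection `SelectionSpec` used for superposition and the lambda
#'   vector (default: C-alpha atoms)
#' @return object of class `ReferencePair`
#' @export
reference_pair <- function(v1, v2, selection = selection_spec("calpha")) {
  stopifnot(inherits(v1, "Structure"), inherits(v2, "Structure"))
  if (n_atoms(v1) != n_atoms(v2) ||
      !all(v1$atoms$name == v2$atoms$name) ||
      !all(v1$atoms$resid == v2$atoms$resid))
    stop("v1 and v2 must share an identical atom list")
  v2a <- superpose(v2, v1, selection)$structure
  idx <- apply_selection(v1, selection)
  dv <- coord_vector(v2a, idx) - coord_vector(v1, idx)
  dnorm <- sqrt(sum(dv^2))
  if (dnorm < 1e-8)
    stop("references coincide on the selection; the lambda axis is undefined")
  structure(list(v1 = v1, v2 = v2, v2_aligned = v2a, selection = selection,
                 axis_norm = dnorm), class = "ReferencePair")
}

#' @export
print.ReferencePair <- function(x, ...) {
  cat(sprintf(
    "ReferencePair: open/locked states, %d atoms, %s selection (%d atoms), axis norm %.2f A\n",
    n_atoms(x$v1), x$selection$mode,
    length(apply_selection(x$v1, x$selection)), x$axis_norm))
  invisible(x)
}

#' Transition coordinate lambda of a single structure
#'
#' The frame is first least-squares superposed onto the open reference on
#' the pair's selection; lambda is then the ratio of coordinate-vector
#' norms `|v - v1| / |v2 - v1|` over the flattened selected coordinates
#' (`method = "norm"`, the literal definition), or the normalized component
#' of `v - v1` along the open-to-locked difference vector
#' (`method = "projection"`). The norm ratio is non-negative by
#' construction and is biased upward by isotropic positional noise (a chi
#' statistic); the projection is signed and recovers the mean position on
#' the axis without that bias.
#'
#' @param frame a `Structure` sharing the references' atom list
#' @param refs a `ReferencePair`
#' @param method `"norm"` (default) or `"projection"`
#' @return numeric lambda (0 at the open, 1 at the locked reference)
#' @export
compute_lambda <- function(frame, refs, method = c("norm", "projection")) {
  stopifnot(inherits(refs, "ReferencePair"))
  method <- match.arg(method)
  fit <- superpose(frame, refs$v1, refs$selection)$structure
  idx <- apply_selection(refs$v1, refs$selection)
  v <- coord_vector(fit, idx)
  v1 <- coord_vector(refs$v1, idx)
  dv <- coord_vector(refs$v2_aligned, idx) - v1
  if (method == "norm") sqrt(sum((v - v1)^2)) / refs$axis_norm
  else sum((v - v1) * dv) / refs$axis_norm^2
}

#' Transition coordinate series over a trajectory
#'
#' @param traj a `Trajectory` sharing the references' atom list
#' @param refs a `ReferencePair`
#' @param method as in [compute_lambda()]
#' @return object of class `LambdaSeries`: list with `values` (one lambda
#'   per frame, order preserved), `mean`, `method` and the selection used
#' @export
lambda_series <- function(traj, refs, method = c("norm", "projection")) {
  stopifnot(inherits(traj, "Trajectory"))
  method <- match.arg(method)
  vals <- vapply(seq_len(n_frames(traj)), function(i) {
    compute_lambda(get_frame(traj, i), refs, method)
  }, numeric(1))
  structure(list(values = vals, mean = mean(vals), method = method,
                 selection = refs$selection), class = "LambdaSeries")
}

#' @export
print.LambdaSeries <- function(x, ...) {
  cat(sprintf("LambdaSeries: %d frames, mean lambda = %.4f (%s)\n",
              length(x$values), x$mean, x$method))
  invisible(x)
}

#' Distance-fluctuation matrix of a trajectory
#'
#' For every selected atom pair (i, j) the entry is the time variance
#' (population variance over frames) of the internal distance d_ij. No
#' superposition is performed: internal distances are invariant under
#' per-frame rigid motion, so the matrix is independent of any reference
#' structure. The diagonal is exactly zero.
#'
#' @param traj a `Trajectory` with at least 2 frames
#' @param sel a `SelectionSpec` (conventionally C-alpha atoms)
#' @return object of class `FluctuationMatrix`: list with `tau` (symmetric
#'   matrix \[Angstrom^2\], labeled by chain/resid/name) and `selection`
#' @export
distance_fluctuation <- function(traj, sel = selection_spec("calpha")) {
  stopifnot(inherits(traj, "Trajectory"))
  if (n_frames(traj) < 2)
    stop("distance fluctuations need at least 2 frames")
  idx <- apply_selection(traj, sel)
  if (length(idx) < 2) stop("need at least 2 selected atoms")
  nf <- n_frames(traj); na <- length(idx)
  ci <- bio3d::atom2xyz(idx)
  # two-pass variance: numerically stable when fluctuations are tiny
  # relative to the distances themselves
  dsum <- matrix(0, na, na)
  dists <- vector("list", nf)
  for (f in seq_len(nf)) {
    xyz <- matrix(traj$xyz[f, ci], ncol = 3, byrow = TRUE)
    dists[[f]] <- as.matrix(dist(xyz))
    dsum <- dsum + dists[[f]]
  }
  dbar <- dsum / nf
  tau <- matrix(0, na, na)
  for (f in seq_len(nf)) tau <- tau + (dists[[f]] - dbar)^2
  tau <- tau / nf
  diag(tau) <- 0
  tau <- (tau + t(tau)) / 2
  lab <- paste0(traj$atoms$chain[idx], traj$atoms$resid[idx], ".",
                traj$atoms$name[idx])
  dimnames(tau) <- list(lab, lab)
  structure(list(tau = tau, selection = sel), class = "FluctuationMatrix")
}

# pairwise superposed-RMSD matrix over frames on a selection
pairwise_rmsd <- function(traj, sel = NULL) {
  idx <- apply_selection(traj, sel)
  ci <- bio3d::atom2xyz(idx)
  nf <- n_frames(traj)
  xyz <- traj$xyz[, ci, drop = FALSE]
  m <- matrix(0, nf, nf)
  for (i in seq_len(nf - 1)) {
    r <- bio3d::rmsd(xyz[i, ], xyz[(i + 1):nf, , drop = FALSE], fit = TRUE)
    m[i, (i + 1):nf] <- r
    m[(i + 1):nf, i] <- r
  }
  m
}

#' GROMOS-style RMSD clustering of a trajectory
#'
#' Frames are clustered on the pairwise least-squares-superposed RMSD:
#' repeatedly the frame with the most neighbors within `cutoff` becomes a
#' cluster centroid, it and its neighbors are assigned and removed, and the
#' procedure recurs on the remainder. Ties in neighbor count are broken by
#' the lowest frame index, so the result is deterministic. The number of
#' clusters is emergent; the cutoff is the only parameter.
#'
#' @param traj a `Trajectory`
#' @param cutoff RMSD criterion \[Angstrom\], default 1.5
#' @param sel a `SelectionSpec` (default all atoms)
#' @return object of class `ClusterResult`: `labels` (cluster id per frame,
#'   ids ordered by decreasing population), `populations` (fractions, sum
#'   1), `centroids` (frame index per cluster) and `cutoff`
#' @export
cluster_trajectory <- function(traj, cutoff = 1.5, sel = NULL) {
  stopifnot(inherits(traj, "Trajectory"))
  if (cutoff <= 0) stop("cutoff must be > 0")
  nf <- n_frames(traj)
  m <- pairwise_rmsd(traj, sel)
  nbr <- m <= cutoff                      # includes self
  remaining <- rep(TRUE, nf)
  labels <- integer(nf)
  centroids <- integer(0)
  cl <- 0L
  while (any(remaining)) {
    counts <- colSums(nbr[remaining, , drop = FALSE])
    counts[!remaining] <- -1L
    center <- which.max(counts)           # which.max takes the lowest index
    members <- which(remaining & nbr[, center])
    cl <- cl + 1L
    labels[members] <- cl
    centroids[cl] <- center
    remaining[members] <- FALSE
  }
  sizes <- tabulate(labels, nbins = cl)
  ord <- order(-sizes, seq_len(cl))       # descending population, stable
  relab <- integer(cl); relab[ord] <- seq_len(cl)
  labels <- relab[labels]
  centroids <- centroids[ord]
  populations <- sizes[ord] / nf
  structure(list(labels = labels, populations = populations,
                 centroids = centroids, cutoff = cutoff, rmsd_matrix = m),
            class = "ClusterResult")
}

#' @export
print.ClusterResult <- function(x, ...) {
  cat(sprintf("ClusterResult: %d frames in %d clusters (cutoff %.2f A)\n",
              length(x$labels), length(x$populations), x$cutoff))
  cat("populations:", paste(sprintf("%.3f", x$populations), collapse = " "),
      "\n")
  invisible(x)
}
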