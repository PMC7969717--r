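#' @importFrom stats rnorm runif sd var setNames dist prcomp
#' @importFrom utils read.delim write.table head packageVersion modifyList
NULL

# Units used throughout: coordinates in Angstrom, energies in kcal/mol,
# charges in elementary charge e, potentials in kBT/e (T = 300 K unless
# stated). Residue numbering is 1-based as in PDB files; atom indices into
# a Structure are 1-based (R convention).

#' Construct a molecular structure
#'
#' A `Structure` is the unit of all geometry in the package: an ordered
#' atom table with coordinates and optional per-atom nonbonded parameters.
#' Atom order is significant — it defines the flattened coordinate-vector
#' order used by the transition coordinate, superposition and the elastic
#' network model.
#'
#' @param atoms data.frame with columns `name`, `element`, `resid`
#'   (integer, 1-based), `resname`, `chain`, `x`, `y`, `z` and optionally
#'   `charge` \[e\], `sigma` \[Angstrom\], `epsilon` \[kcal/mol\],
#'   `radius` \[Angstrom\]. Missing optional columns are filled with `NA`.
#' @param metadata named list of free-form metadata.
#' @return object of class `Structure`.
#' @export
new_structure <- function(atoms, metadata = list()) {
  req <- c("name", "element", "resid", "resname", "chain", "x", "y", "z")
  miss <- setdiff(req, names(atoms))
  if (length(miss) > 0)
    stop("atom table missing required column(s): ", paste(miss, collapse = ", "))
  if (nrow(atoms) < 1) stop("a Structure needs at least one atom")
  for (opt in c("charge", "sigma", "epsilon", "radius"))
    if (is.null(atoms[[opt]])) atoms[[opt]] <- NA_real_
  atoms$resid <- as.integer(atoms$resid)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("atom positions must be finite")
  if (any(!is.na(atoms$radius) & atoms$radius <= 0))
    stop("atom radius must be > 0 when present")
  if (any(!is.na(atoms$epsilon) & atoms$epsilon < 0))
    stop("lj epsilon must be >= 0 when present")
  # residue ids must be non-decreasing within a chain
  for (ch in unique(atoms$chain)) {
    r <- atoms$resid[atoms$chain == ch]
    if (any(diff(r) < 0))
      stop("residue ids must be non-decreasing within chain ", ch)
  }
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, metadata = metadata), class = "Structure")
}

#' Number of atoms in a Structure or per frame of a Trajectory
#' @param x a `Structure` or `Trajectory`
#' @return integer atom count
#' @export
n_atoms <- function(x) {
  if (inherits(x, "Structure")) nrow(x$atoms)
  else if (inherits(x, "Trajectory")) nrow(x$atoms)
  else stop("n_atoms() expects a Structure or Trajectory")
}

#' Extract the N x 3 coordinate matrix of a Structure
#' @param s a `Structure`
#' @return numeric matrix with one row per atom (Angstrom)
#' @export
coords <- function(s) {
  stopifnot(inherits(s, "Structure"))
  as.matrix(s$atoms[, c("x", "y", "z")])
}

#' Replace the coordinates of a Structure
#' @param s a `Structure`
#' @param xyz N x 3 matrix or length-3N vector (x1,y1,z1,...)
#' @return the modified `Structure`
#' @export
set_coords <- function(s, xyz) {
  stopifnot(inherits(s, "Structure"))
  if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3, byrow = TRUE)
  if (nrow(xyz) != n_atoms(s)) stop("coordinate count does not match atom count")
  s$atoms$x <- xyz[, 1]; s$atoms$y <- xyz[, 2]; s$atoms$z <- xyz[, 3]
  s
}

#' Flatten coordinates to a single vector (x1,y1,z1,x2,...)
#' @param s a `Structure`
#' @param idx optional atom indices to include (default all)
#' @return numeric vector of length 3*length(idx)
#' @export
coord_vector <- function(s, idx = NULL) {
  xyz <- coords(s)
  if (!is.null(idx)) xyz <- xyz[idx, , drop = FALSE]
  as.vector(t(xyz))
}

#' @export
print.Structure <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("Structure: %d atoms, %d residues, chains: %s\n",
              nrow(a), length(unique(paste(a$chain, a$resid))),
              paste(unique(a$chain), collapse = ",")))
  invisible(x)
}

#' Construct a trajectory
#'
#' A `Trajectory` is an ordered set of frames over a fixed atom list. The
#' atom identity (names, residues, order) is shared by all frames; only the
#' coordinates change.
#'
#' @param atoms atom table as in [new_structure()] (coordinates ignored) or a
#'   template `Structure`.
#' @param xyz frames-by-3N coordinate matrix, one row per frame, columns in
#'   (x1,y1,z1,x2,...) order.
#' @param metadata named list.
#' @return object of class `Trajectory`.
#' @export
new_trajectory <- function(atoms, xyz, metadata = list()) {
  if (inherits(atoms, "Structure")) atoms <- atoms$atoms
  xyz <- as.matrix(xyz)
  if (nrow(xyz) < 1) stop("a Trajectory needs at least one frame")
  if (ncol(xyz) != 3L * nrow(atoms))
    stop("coordinate columns (", ncol(xyz), ") do not match 3 x atom count (",
         3L * nrow(atoms), ")")
  if (!all(is.finite(xyz))) stop("trajectory coordinates must be finite")
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, xyz = xyz, metadata = metadata),
            class = "Trajectory")
}

#' Number of frames in a Trajectory
#' @param traj a `Trajectory`
#' @return integer frame count
#' @export
n_frames <- function(traj) {
  stopifnot(inherits(traj, "Trajectory"))
  nrow(traj$xyz)
}

#' Extract one frame of a Trajectory as a Structure
#' @param traj a `Trajectory`
#' @param i frame index (1-based)
#' @return a `Structure`
#' @export
get_frame <- function(traj, i) {
  stopifnot(inherits(traj, "Trajectory"))
  if (i < 1 || i > n_frames(traj)) stop("frame index out of range: ", i)
  a <- traj$atoms
  xyz <- matrix(traj$xyz[i, ], ncol = 3, byrow = TRUE)
  a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
  structure(list(atoms = a, metadata = traj$metadata), class = "Structure")
}

#' @export
print.Trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d frames x %d atoms\n", nrow(x$xyz), nrow(x$atoms)))
  invisible(x)
}

#' Atom selections
#'
#' A `SelectionSpec` names an ordered atom subset of any Structure it is
#' applied to. The `calpha` mode (the default throughout the conformational
#' and normal-mode analyses) selects atoms named `CA`, one per amino-acid
#' residue.
#'
#' @param mode one of `"all"`, `"calpha"`, `"residue_range"`, `"name_list"`.
#' @param from,to residue bounds for `residue_range` (inclusive, 1-based).
#' @param names character vector of atom names for `name_list`.
#' @param chain optional chain restriction (any mode).
#' @return object of class `SelectionSpec`.
#' @export
selection_spec <- function(mode = c("all", "calpha", "residue_range", "name_list"),
                           from = NULL, to = NULL, names = NULL, chain = NULL) {
  mode <- match.arg(mode)
  if (mode == "residue_range" && (is.null(from) || is.null(to)))
    stop("residue_range selection needs 'from' and 'to'")
  if (mode == "name_list" && is.null(names))
    stop("name_list selection needs 'names'")
  structure(list(mode = mode, from = from, to = to, names = names,
                 chain = chain), class = "SelectionSpec")
}

#' Resolve a selection on a Structure
#'
#' @param s a `Structure` (or `Trajectory`, resolved on its atom table).
#' @param sel a `SelectionSpec`; `NULL` means all atoms.
#' @return strictly increasing integer vector of atom indices (1-based).
#' @export
apply_selection <- function(s, sel = NULL) {
  a <- if (inherits(s, "Structure") || inherits(s, "Trajectory")) s$atoms
       else stop("apply_selection() expects a Structure or Trajectory")
  if (is.null(sel)) return(seq_len(nrow(a)))
  stopifnot(inherits(sel, "SelectionSpec"))
  keep <- rep(TRUE, nrow(a))
  if (!is.null(sel$chain)) keep <- keep & a$chain %in% sel$chain
  idx <- switch(sel$mode,
    all = which(keep),
    calpha = which(keep & a$name == "CA"),
    residue_range = which(keep & a$resid >= sel$from & a$resid <= sel$to),
    name_list = which(keep & a$name %in% sel$names))
  if (length(idx) == 0)
    stop("selection (mode '", sel$mode, "') resolves to no atoms")
  sort(idx)
}
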