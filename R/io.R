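# Readers/writers for PDB (via bio3d), XYZ, and the per-atom parameter
# sidecar (tab-separated: chain, resid, atom, charge, sigma, epsilon, radius).

# Pre-scan a PDB file: reject insertion codes, malformed ATOM/HETATM records
# (with the offending line number) and inconsistent atom sets across MODELs.
validate_pdb_lines <- function(lines, path) {
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_atom)) stop("no ATOM/HETATM records in ", path)
  at_lines <- which(is_atom)
  for (ln in at_lines) {
    l <- lines[ln]
    if (nchar(l) < 54)
      stop("malformed ATOM record (too short) at line ", ln, " of ", path)
    for (fld in list(c(31, 38), c(39, 46), c(47, 54))) {
      v <- suppressWarnings(as.numeric(substr(l, fld[1], fld[2])))
      if (is.na(v))
        stop("malformed ATOM record (bad coordinate field) at line ", ln,
             " of ", path)
    }
    icode <- substr(l, 27, 27)
    if (icode != " ")
      stop("insertion code '", icode, "' at line ", ln, " of ", path,
           " is not supported; renumber residues first")
  }
  # per-MODEL atom-name sequences must agree
  model_starts <- which(substr(lines, 1, 5) == "MODEL")
  if (length(model_starts) > 1) {
    model_of <- findInterval(at_lines, model_starts)
    keys <- paste(substr(lines[at_lines], 13, 27))
    ref <- keys[model_of == 1]
    for (m in seq_along(model_starts)[-1]) {
      k <- keys[model_of == m]
      if (length(k) != length(ref) || !all(k == ref))
        stop("inconsistent atom set in frame ", m, " of ", path,
             " (expected ", length(ref), " atoms matching frame 1, got ",
             length(k), ")")
    }
  }
  invisible(length(model_starts))
}

bio3d_to_atoms <- function(atom_df) {
  # bio3d column names: elety = atom name, resid = residue name, resno = id
  a <- data.frame(
    name = atom_df$elety,
    element = ifelse(is.na(atom_df$elesy) | atom_df$elesy == "",
                     substr(trimws(atom_df$elety), 1, 1), trimws(atom_df$elesy)),
    resid = atom_df$resno,
    resname = atom_df$resid,
    chain = ifelse(is.na(atom_df$chain), "A", atom_df$chain),
    x = atom_df$x, y = atom_df$y, z = atom_df$z,
    stringsAsFactors = FALSE)
  # keep the first alternate location only
  if (!is.null(atom_df$alt)) {
    key <- paste(a$chain, a$resid, a$name)
    a <- a[!duplicated(key), , drop = FALSE]
  }
  rownames(a) <- NULL
  a
}

read_xyz_blocks <- function(lines, path) {
  frames <- list()
  i <- 1L; nline <- length(lines)
  while (i <= nline) {
    if (trimws(lines[i]) == "") { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1)
      stop("malformed XYZ count line at line ", i, " of ", path)
    if (i + 1L + n > nline)
      stop("truncated XYZ frame starting at line ", i, " of ", path)
    block <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(block), "[[:space:]]+")
    bad <- which(vapply(parts, length, 1L) < 4L)
    if (length(bad) > 0)
      stop("malformed XYZ atom record at line ", i + 1L + bad[1], " of ", path)
    el <- vapply(parts, `[`, "", 1L)
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (!all(is.finite(xyz)))
      stop("non-numeric coordinate in XYZ frame starting at line ", i,
           " of ", path)
    frames[[length(frames) + 1L]] <- list(element = el, xyz = xyz,
                                          comment = lines[i + 1L])
    i <- i + 2L + n
  }
  if (length(frames) == 0) stop("no frames found in ", path)
  frames
}

xyz_frames_to_atoms <- function(fr) {
  data.frame(
    name = fr$element, element = fr$element,
    resid = seq_along(fr$element), resname = "UNK", chain = "A",
    x = fr$xyz[, 1], y = fr$xyz[, 2], z = fr$xyz[, 3],
    stringsAsFactors = FALSE)
}

guess_dialect <- function(path) {
  if (grepl("\\.xyz$", path, ignore.case = TRUE)) "xyz" else "pdb"
}

#' Read a structure from a PDB or XYZ file
#'
#' For multi-model PDB files the first model is returned; use
#' [read_trajectory()] for the full ensemble. Alternate locations keep the
#' first variant; insertion codes are rejected.
#'
#' @param path file path.
#' @param dialect `"pdb"` or `"xyz"`; default guessed from the extension.
#' @return a `Structure` (coordinates in Angstrom).
#' @export
read_structure <- function(path, dialect = guess_dialect(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) stop("empty file: ", path)
  dialect <- match.arg(dialect, c("pdb", "xyz"))
  if (dialect == "pdb") {
    validate_pdb_lines(lines, path)
    pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
    new_structure(bio3d_to_atoms(pdb$atom), metadata = list(source = path))
  } else {
    fr <- read_xyz_blocks(lines, path)[[1]]
    new_structure(xyz_frames_to_atoms(fr), metadata = list(source = path))
  }
}

#' Read a trajectory from a multi-model PDB or concatenated XYZ file
#'
#' All frames must share an identical atom list; a frame that deviates is
#' reported by index.
#'
#' @inheritParams read_structure
#' @return a `Trajectory`.
#' @export
read_trajectory <- function(path, dialect = guess_dialect(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) stop("empty file: ", path)
  dialect <- match.arg(dialect, c("pdb", "xyz"))
  if (dialect == "pdb") {
    validate_pdb_lines(lines, path)
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    atoms <- bio3d_to_atoms(pdb$atom)
    xyz <- pdb$xyz
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
    new_trajectory(atoms, xyz, metadata = list(source = path))
  } else {
    frames <- read_xyz_blocks(lines, path)
    ref <- frames[[1]]$element
    for (k in seq_along(frames)) {
      if (length(frames[[k]]$element) != length(ref) ||
          !all(frames[[k]]$element == ref))
        stop("inconsistent atom set in frame ", k, " of ", path)
    }
    xyz <- do.call(rbind, lapply(frames, function(f) as.vector(t(f$xyz))))
    new_trajectory(xyz_frames_to_atoms(frames[[1]]), xyz,
                   metadata = list(source = path))
  }
}

#' Write a structure to PDB or XYZ
#' @param s a `Structure`
#' @param path output file
#' @param dialect `"pdb"` or `"xyz"`
#' @return `path`, invisibly
#' @export
write_structure <- function(s, path, dialect = guess_dialect(path)) {
  stopifnot(inherits(s, "Structure"))
  dialect <- match.arg(dialect, c("pdb", "xyz"))
  a <- s$atoms
  if (dialect == "pdb") {
    bio3d::write.pdb(file = path, xyz = coord_vector(s),
                     resno = a$resid, resid = a$resname, chain = a$chain,
                     elety = a$name, eleno = seq_len(nrow(a)),
                     elesy = a$element)
  } else {
    writeLines(c(nrow(a), "generated by hapbind",
                 sprintf("%-3s %12.6f %12.6f %12.6f",
                         a$element, a$x, a$y, a$z)), path)
  }
  invisible(path)
}

#' Write a trajectory to multi-model PDB or concatenated XYZ
#' @param traj a `Trajectory`
#' @param path output file
#' @param dialect `"pdb"` or `"xyz"`
#' @return `path`, invisibly
#' @export
write_trajectory <- function(traj, path, dialect = guess_dialect(path)) {
  stopifnot(inherits(traj, "Trajectory"))
  dialect <- match.arg(dialect, c("pdb", "xyz"))
  a <- traj$atoms
  if (dialect == "pdb") {
    bio3d::write.pdb(file = path, xyz = traj$xyz,
                     resno = a$resid, resid = a$resname, chain = a$chain,
                     elety = a$name, eleno = seq_len(nrow(a)),
                     elesy = a$element)
  } else {
    out <- character(0)
    for (i in seq_len(n_frames(traj))) {
      xyz <- matrix(traj$xyz[i, ], ncol = 3, byrow = TRUE)
      out <- c(out, nrow(a), sprintf("frame %d", i),
               sprintf("%-3s %12.6f %12.6f %12.6f",
                       a$element, xyz[, 1], xyz[, 2], xyz[, 3]))
    }
    writeLines(out, path)
  }
  invisible(path)
}

#' Read a per-atom parameter sidecar
#'
#' Tab-separated with header columns `chain`, `resid`, `atom`, `charge`
#' \[e\], `sigma` \[Angstrom\], `epsilon` \[kcal/mol\], `radius`
#' \[Angstrom\]. Every (chain, resid, atom) key must be unique.
#'
#' @param path file path
#' @return data.frame of class `ParameterTable`
#' @export
read_parameters <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  req <- c("chain", "resid", "atom", "charge", "sigma", "epsilon", "radius")
  miss <- setdiff(req, names(tab))
  if (length(miss) > 0)
    stop("parameter file missing required column(s): ",
         paste(miss, collapse = ", "))
  key <- paste(tab$chain, tab$resid, tab$atom, sep = "/")
  if (anyDuplicated(key))
    stop("duplicate parameter key(s): ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  class(tab) <- c("ParameterTable", "data.frame")
  tab
}

#' Write a per-atom parameter sidecar
#' @param params `ParameterTable` or a `Structure` whose atom table carries
#'   parameters
#' @param path output file
#' @return `path`, invisibly
#' @export
write_parameters <- function(params, path) {
  if (inherits(params, "Structure")) {
    a <- params$atoms
    params <- data.frame(chain = a$chain, resid = a$resid, atom = a$name,
                         charge = a$charge, sigma = a$sigma,
                         epsilon = a$epsilon, radius = a$radius,
                         stringsAsFactors = FALSE)
  }
  write.table(params, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Attach per-atom parameters to a Structure
#'
#' Atoms without a matching (chain, resid, atom name) row keep unset (`NA`)
#' parameters; geometry-only workflows tolerate that, energetics operations
#' error when they touch an unparameterized atom. The number of unmatched
#' atoms is stored in `metadata$n_unmatched` and reported via a message.
#'
#' @param s a `Structure`
#' @param params a `ParameterTable` from [read_parameters()]
#' @return the `Structure` with parameter columns filled
#' @export
attach_parameters <- function(s, params) {
  stopifnot(inherits(s, "Structure"))
  a <- s$atoms
  key_s <- paste(a$chain, a$resid, a$name, sep = "/")
  key_p <- paste(params$chain, params$resid, params$atom, sep = "/")
  m <- match(key_s, key_p)
  hit <- !is.na(m)
  for (col in c("charge", "sigma", "epsilon", "radius"))
    a[[col]][hit] <- params[[col]][m[hit]]
  s$atoms <- a
  s$metadata$n_unmatched <- sum(!hit)
  if (sum(!hit) > 0)
    message(sum(!hit), " atom(s) had no matching parameter row")
  s
}
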