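# MM/PBSA binding-energy engine: single-trajectory protocol, per-residue
# decomposition and computational alanine scanning.

#' Energy ledger for one system
#'
#' @param E_bonded,E_vdW,E_elec,G_polar,G_nonpolar term values \[kcal/mol\]
#' @param TS entropy term `T*S` \[kcal/mol\]
#' @param include_entropy include `-TS` in the total
#' @return object of class `EnergyBreakdown` with `G_total` equal to the
#'   sum of the five terms (minus `TS` only when entropy is on)
#' @export
energy_breakdown <- function(E_bonded = 0, E_vdW = 0, E_elec = 0,
                             G_polar = 0, G_nonpolar = 0, TS = 0,
                             include_entropy = FALSE) {
  g <- E_bonded + E_vdW + E_elec + G_polar + G_nonpolar
  if (include_entropy) g <- g - TS
  structure(list(E_bonded = E_bonded, E_vdW = E_vdW, E_elec = E_elec,
                 G_polar = G_polar, G_nonpolar = G_nonpolar, TS = TS,
                 include_entropy = include_entropy, G_total = g),
            class = "EnergyBreakdown")
}

#' @export
print.EnergyBreakdown <- function(x, ...) {
  for (t in c("E_bonded", "E_vdW", "E_elec", "G_polar", "G_nonpolar",
              "G_total"))
    cat(sprintf("%-11s %12.4f kcal/mol\n", t, x[[t]]))
  invisible(x)
}

#' Extract a sub-structure by atom indices
#' @param s a `Structure`
#' @param idx atom indices to keep (order preserved)
#' @return a `Structure`
#' @export
subset_structure <- function(s, idx) {
  stopifnot(inherits(s, "Structure"))
  new_structure(s$atoms[idx, , drop = FALSE], metadata = s$metadata)
}

# keep bonded terms fully inside `idx` and remap their atom indices;
# error if a term crosses the boundary between kept and dropped atoms
# (crossing terms would break the single-trajectory cancellation)
remap_terms <- function(terms, idx, allow_partial = FALSE) {
  if (is.null(terms)) return(NULL)
  map <- integer(0)
  map[idx] <- seq_along(idx)
  filter_df <- function(df, cols) {
    if (nrow(df) == 0) return(df)
    m <- as.matrix(df[, cols, drop = FALSE])
    inside <- matrix(m %in% idx, nrow(m))
    all_in <- rowSums(inside) == ncol(inside)
    any_in <- rowSums(inside) > 0
    if (!allow_partial && any(any_in & !all_in))
      stop("a bonded term crosses the atom partition")
    df <- df[all_in, , drop = FALSE]
    for (cl in cols) df[[cl]] <- map[df[[cl]]]
    df
  }
  bonded_terms(bonds = filter_df(terms$bonds, c("i", "j")),
               angles = filter_df(terms$angles, c("i", "j", "k")),
               dihedrals = filter_df(terms$dihedrals, c("i", "j", "k", "l")))
}

#' MM/PBSA binding free energy with per-residue decomposition
#'
#' Single-trajectory protocol: the unbound protein and ligand geometries
#' are extracted unchanged from the complex, so every bonded term cancels
#' in the difference and `delta` for the MM terms equals the cross-group
#' interaction exactly. For every term,
#' `delta = complex - (protein + ligand)`. The decomposition assigns
#' pairwise MM energies half to each partner atom, the polar term per atom
#' as `1/2 q_i (phi_complex - phi_free)`, and the nonpolar term per atom as
#' `gamma (SASA_complex - SASA_free)` with the constant offset's net
#' contribution spread uniformly; per-atom contributions sum to the
#' per-residue table and to `delta$G_total` exactly.
#'
#' @param complex a fully parameterized `Structure`
#' @param protein_sel,ligand_sel disjoint atom index vectors (or
#'   `SelectionSpec`s) that together cover every atom of `complex`
#' @param terms optional [bonded_terms()] for the complex
#' @param cfg an [energy_config()]
#' @return object of class `BindingResult`: `complex`, `protein`, `ligand`,
#'   `delta` (each an `EnergyBreakdown`), `per_atom` (data.frame of atom
#'   contributions to the binding energy) and `per_residue` (data.frame
#'   with one row per residue, sorted by contribution)
#' @export
mmpbsa <- function(complex, protein_sel, ligand_sel, terms = NULL,
                   cfg = energy_config()) {
  stopifnot(inherits(complex, "Structure"))
  ip <- resolve_group(complex, protein_sel)
  il <- resolve_group(complex, ligand_sel)
  if (length(intersect(ip, il)) > 0)
    stop("protein and ligand selections overlap")
  if (!setequal(c(ip, il), seq_len(n_atoms(complex))))
    stop("protein and ligand selections must partition the complex atoms")
  prot <- subset_structure(complex, ip)
  lig <- subset_structure(complex, il)
  terms_p <- remap_terms(terms, ip)
  terms_l <- remap_terms(terms, il)
  eb_bond <- function(s, tm) if (is.null(tm)) 0 else bonded_energy(s, tm)
  # MM pairwise matrices: internal blocks are shared by bound and free
  # states, the cross block is the interaction
  el_pp <- coulomb_energy(complex, cfg, ip, ip)
  el_ll <- coulomb_energy(complex, cfg, il, il)
  el_cross_m <- coulomb_pair_matrix(complex, cfg, ip, il)
  lj_pp <- lj_energy(complex, cfg, ip, ip)
  lj_ll <- lj_energy(complex, cfg, il, il)
  lj_cross_m <- lj_pair_matrix(complex, cfg, ip, il)
  el_cross <- sum(el_cross_m); lj_cross <- sum(lj_cross_m)
  pb_c <- pb_polar_energy(complex, cfg, per_atom = TRUE)
  pb_p <- pb_polar_energy(prot, cfg, per_atom = TRUE)
  pb_l <- pb_polar_energy(lig, cfg, per_atom = TRUE)
  sa_c <- sasa(complex, cfg)
  sa_p <- sasa(prot, cfg)
  sa_l <- sasa(lig, cfg)
  gnp <- function(total) cfg$sasa_gamma * total + cfg$sasa_offset
  mk <- function(bonded, vdw, elec, pol, np)
    energy_breakdown(bonded, vdw, elec, pol, np, TS = cfg$entropy_TS,
                     include_entropy = cfg$include_entropy)
  eb_c <- mk(eb_bond(complex, terms), lj_pp + lj_ll + lj_cross,
             el_pp + el_ll + el_cross, pb_c$G_polar, gnp(sa_c$total))
  eb_p <- mk(eb_bond(prot, terms_p), lj_pp, el_pp, pb_p$G_polar,
             gnp(sa_p$total))
  eb_l <- mk(eb_bond(lig, terms_l), lj_ll, el_ll, pb_l$G_polar,
             gnp(sa_l$total))
  delta <- mk(eb_c$E_bonded - eb_p$E_bonded - eb_l$E_bonded,
              lj_cross, el_cross,
              pb_c$G_polar - pb_p$G_polar - pb_l$G_polar,
              gnp(sa_c$total) - gnp(sa_p$total) - gnp(sa_l$total))
  # per-atom contributions (ordered as the complex atoms)
  n <- n_atoms(complex)
  d_elec <- numeric(n); d_vdw <- numeric(n)
  d_elec[ip] <- rowSums(el_cross_m) / 2
  d_elec[il] <- colSums(el_cross_m) / 2
  d_vdw[ip] <- rowSums(lj_cross_m) / 2
  d_vdw[il] <- colSums(lj_cross_m) / 2
  d_pol <- pb_c$per_atom
  d_pol[ip] <- d_pol[ip] - pb_p$per_atom
  d_pol[il] <- d_pol[il] - pb_l$per_atom
  d_np <- cfg$sasa_gamma * sa_c$per_atom
  d_np[ip] <- d_np[ip] - cfg$sasa_gamma * sa_p$per_atom
  d_np[il] <- d_np[il] - cfg$sasa_gamma * sa_l$per_atom
  d_np <- d_np - cfg$sasa_offset / n        # net offset delta = -b
  a <- complex$atoms
  per_atom <- data.frame(chain = a$chain, resid = a$resid,
                         resname = a$resname, atom = a$name,
                         elec = d_elec, vdw = d_vdw, polar = d_pol,
                         nonpolar = d_np,
                         total = d_elec + d_vdw + d_pol + d_np,
                         stringsAsFactors = FALSE)
  key <- paste(a$chain, a$resid, sep = ":")
  agg <- rowsum(per_atom[, c("elec", "vdw", "polar", "nonpolar", "total")],
                key, reorder = FALSE)
  first <- !duplicated(key)
  per_residue <- data.frame(chain = a$chain[first], resid = a$resid[first],
                            resname = a$resname[first], agg,
                            stringsAsFactors = FALSE)
  per_residue <- per_residue[order(per_residue$total), , drop = FALSE]
  rownames(per_residue) <- NULL
  structure(list(complex = eb_c, protein = eb_p, ligand = eb_l,
                 delta = delta, per_atom = per_atom,
                 per_residue = per_residue),
            class = "BindingResult")
}

#' @export
print.BindingResult <- function(x, ...) {
  cat("MM/PBSA binding energy (delta = complex - protein - ligand):\n")
  print(x$delta)
  cat("top contributing residues:\n")
  print(head(x$per_residue, 5))
  invisible(x)
}

#' MM/PBSA averaged over trajectory frames
#'
#' Every term is computed per frame and reported as arithmetic mean and
#' standard deviation over frames; per-frame values are retained.
#'
#' @param traj a `Trajectory` carrying the complex atom table (with
#'   parameters)
#' @param protein_sel,ligand_sel as in [mmpbsa()]
#' @param terms,cfg as in [mmpbsa()]
#' @param frames frame indices to evaluate (default: all)
#' @return list with `summary` (term, mean, sd), `per_frame` (one row per
#'   frame) and `results` (list of per-frame `BindingResult`s)
#' @export
mmpbsa_trajectory <- function(traj, protein_sel, ligand_sel, terms = NULL,
                              cfg = energy_config(), frames = NULL) {
  stopifnot(inherits(traj, "Trajectory"))
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  res <- lapply(frames, function(f) {
    mmpbsa(get_frame(traj, f), protein_sel, ligand_sel, terms, cfg)
  })
  tn <- c("E_bonded", "E_vdW", "E_elec", "G_polar", "G_nonpolar", "G_total")
  pf <- do.call(rbind, lapply(res, function(r)
    as.data.frame(r$delta[tn])))
  pf <- cbind(frame = frames, pf)
  summ <- data.frame(term = tn,
                     mean = vapply(tn, function(t) mean(pf[[t]]), 0),
                     sd = vapply(tn, function(t) sd(pf[[t]]), 0))
  rownames(summ) <- NULL
  list(summary = summ, per_frame = pf, results = res)
}

#' Truncate residues to alanine
#'
#' Side-chain atoms beyond the beta carbon are deleted; the beta carbon is
#' retyped to alanine parameters with its charge set so the residue is
#' net-neutral (the negative of the summed charges of the retained backbone
#' atoms). Glycine (no beta carbon) and proline (backbone-coupled ring) are
#' rejected.
#'
#' @param s a `Structure`
#' @param residues character vector `"chain:resid"` (e.g. `"A:5"`)
#' @return list with `structure` (mutated) and `kept` (original atom
#'   indices retained, for remapping selections and bonded terms)
#' @export
ala_mutate <- function(s, residues) {
  stopifnot(inherits(s, "Structure"))
  a <- s$atoms
  keep_names <- c("N", "CA", "C", "O", "CB", "H", "HA", "OXT")
  drop <- logical(nrow(a))
  for (rs in residues) {
    parts <- strsplit(rs, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2)
      stop("residue spec must be 'chain:resid', got '", rs, "'")
    ri <- which(a$chain == parts[1] & a$resid == as.integer(parts[2]))
    if (length(ri) == 0) stop("residue ", rs, " not found")
    rn <- a$resname[ri[1]]
    if (rn == "GLY")
      stop("cannot truncate glycine ", rs, " to alanine: it has no ",
           "beta carbon")
    if (rn == "PRO")
      stop("cannot truncate proline ", rs, ": its side chain is part of ",
           "the backbone ring")
    if (!"CB" %in% a$name[ri])
      stop("residue ", rs, " has no CB atom")
    sel_drop <- ri[!a$name[ri] %in% keep_names]
    drop[sel_drop] <- TRUE
    cb <- ri[a$name[ri] == "CB"]
    others <- setdiff(ri[a$name[ri] %in% keep_names], cb)
    a$charge[cb] <- -sum(a$charge[others])
    a$sigma[cb] <- 3.60; a$epsilon[cb] <- 0.07; a$radius[cb] <- 1.70
    a$resname[ri] <- "ALA"
  }
  kept <- which(!drop)
  s$atoms <- a[kept, , drop = FALSE]
  list(structure = new_structure(s$atoms, metadata = s$metadata), kept = kept)
}

#' Computational alanine scan
#'
#' Each element of `mutations` (a character vector of `"chain:resid"`
#' residues, applied simultaneously) yields one mutant: the residues are
#' truncated to alanine with [ala_mutate()] and the binding energy is
#' re-evaluated on the unchanged backbone geometry.
#'
#' @param complex a fully parameterized `Structure`
#' @param mutations list of character vectors; each entry defines one
#'   mutant (single or multiple simultaneous truncations)
#' @param protein_sel,ligand_sel,terms,cfg as in [mmpbsa()]
#' @return list with `wild_type` (`BindingResult`), `mutants` (named list
#'   of `BindingResult`s) and `ddG` (data.frame of
#'   `delta delta G = dG_mutant - dG_wildtype`)
#' @export
alanine_scan <- function(complex, mutations, protein_sel, ligand_sel,
                         terms = NULL, cfg = energy_config()) {
  ip <- resolve_group(complex, protein_sel)
  il <- resolve_group(complex, ligand_sel)
  wt <- mmpbsa(complex, ip, il, terms, cfg)
  if (!is.list(mutations)) mutations <- list(mutations)
  names(mutations) <- vapply(mutations, paste, "", collapse = "+")
  mut_res <- lapply(mutations, function(rset) {
    m <- ala_mutate(complex, rset)
    keep <- m$kept
    map <- integer(n_atoms(complex)); map[keep] <- seq_along(keep)
    mmpbsa(m$structure, map[intersect(ip, keep)], map[intersect(il, keep)],
           remap_terms(terms, keep, allow_partial = TRUE), cfg)
  })
  ddg <- data.frame(mutant = names(mutations),
                    dG_wildtype = wt$delta$G_total,
                    dG_mutant = vapply(mut_res, function(r)
                      r$delta$G_total, 0),
                    stringsAsFactors = FALSE)
  ddg$ddG <- ddg$dG_mutant - ddg$dG_wildtype
  rownames(ddg) <- NULL
  list(wild_type = wt, mutants = mut_res, ddG = ddg)
}
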