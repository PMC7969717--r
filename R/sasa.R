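# Shrake-Rupley solvent-accessible surface area.

# deterministic, near-uniform unit-sphere points (golden-section spiral)
sphere_points <- function(n) {
  i <- seq_len(n)
  z <- 1 - (2 * i - 1) / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- i * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Each atom is inflated by the probe radius and sampled with a fixed
#' deterministic sphere-point set; points buried inside any neighbor's
#' inflated sphere are discarded. The per-atom area is the exposed point
#' fraction times the inflated-sphere area.
#'
#' @param s a `Structure` with radii on all atoms
#' @param cfg an [energy_config()] (probe radius and point count)
#' @param idx optional atom subset to compute areas for (in the context of
#'   the whole structure)
#' @return list with `total` \[Angstrom^2\] and `per_atom` areas
#' @export
sasa <- function(s, cfg = energy_config(), idx = NULL) {
  stopifnot(inherits(s, "Structure"))
  a <- s$atoms
  if (anyNA(a$radius))
    stop("missing radius for atom(s) ",
         paste(head(which(is.na(a$radius)), 3), collapse = ", "))
  if (is.null(idx)) idx <- seq_len(nrow(a))
  xyz <- coords(s)
  rr <- a$radius + cfg$sasa_probe
  pts <- sphere_points(cfg$sasa_points)
  per <- numeric(length(idx))
  for (t in seq_along(idx)) {
    i <- idx[t]
    p <- sweep(pts * rr[i], 2, xyz[i, ], "+")
    nbr <- which(sqrt(rowSums(sweep(xyz, 2, xyz[i, ])^2)) < rr + rr[i])
    nbr <- setdiff(nbr, i)
    exposed <- rep(TRUE, nrow(p))
    for (j in nbr) {
      d2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
            (p[, 3] - xyz[j, 3])^2
      exposed <- exposed & d2 > rr[j]^2
      if (!any(exposed)) break
    }
    per[t] <- 4 * pi * rr[i]^2 * mean(exposed)
  }
  list(total = sum(per), per_atom = per)
}
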