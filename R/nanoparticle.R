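# Nanoparticle surface characterization: accessible-surface sampling,
# electrostatic potential maps in kBT/e, sign-patch classification and
# charge-density series across particle sizes.

#' Sample the accessible surface of a nanoparticle
#'
#' Union-of-spheres outer surface (site radius + probe) sampled with the
#' same deterministic sphere-point sets used for SASA; points buried inside
#' any other site's inflated sphere are discarded.
#'
#' @param p a `Nanoparticle`
#' @param probe probe radius \[Angstrom\], default 1.4
#' @param density target points per Angstrom^2, default 1
#' @param site_radius site sphere radius \[Angstrom\], default 1.5
#' @return list with `points` (M x 3), `site` (owning site index per
#'   point), `weight` (area per point, A^2), `area` (total, A^2)
#' @export
surface_points <- function(p, probe = 1.4, density = 1, site_radius = 1.5) {
  stopifnot(inherits(p, "Nanoparticle"))
  if (density <= 0) stop("density must be > 0")
  xyz <- as.matrix(p$sites[, c("x", "y", "z")])
  n <- nrow(xyz)
  r <- site_radius + probe
  npts <- max(8L, round(density * 4 * pi * r^2))
  pts0 <- sphere_points(npts) * r
  out <- list(); owner <- list()
  for (i in seq_len(n)) {
    pp <- sweep(pts0, 2, xyz[i, ], "+")
    keep <- rep(TRUE, npts)
    d_site <- sqrt(rowSums(sweep(xyz, 2, xyz[i, ])^2))
    for (j in which(d_site < 2 * r & seq_len(n) != i)) {
      d2 <- (pp[, 1] - xyz[j, 1])^2 + (pp[, 2] - xyz[j, 2])^2 +
            (pp[, 3] - xyz[j, 3])^2
      keep <- keep & d2 > r^2
    }
    if (any(keep)) {
      out[[length(out) + 1L]] <- pp[keep, , drop = FALSE]
      owner[[length(owner) + 1L]] <- rep(i, sum(keep))
    }
  }
  points <- do.call(rbind, out)
  w <- 4 * pi * r^2 / npts
  list(points = points, site = unlist(owner), weight = w,
       area = w * nrow(points))
}

#' Electrostatic potential map of a nanoparticle surface
#'
#' Vacuum Coulomb potential of the fixed site charges,
#' `phi(x) = k_C sum q_i / |x - r_i|`, converted to kBT/e at the given
#' temperature (1 kBT at 300 K = 0.59616 kcal/mol). An optional Debye
#' screening length can be applied via `ionic_strength`.
#'
#' @param p a `Nanoparticle`
#' @param points surface sample list from [surface_points()] (default:
#'   computed with its defaults) or an M x 3 matrix
#' @param temperature \[K\], default 300
#' @param ionic_strength monovalent salt \[mM\] for optional Debye
#'   screening; 0 (default) = unscreened
#' @param solvent_dielectric used only when screening is on
#' @return object of class `SurfaceMap`: `points`, `potentials` \[kBT/e\],
#'   `area` \[nm^2\], `total_charge` \[e\], `charge_density` \[e/nm^2\],
#'   `site` (owning site per point)
#' @export
electrostatic_map <- function(p, points = surface_points(p),
                              temperature = 300, ionic_strength = 0,
                              solvent_dielectric = 80) {
  stopifnot(inherits(p, "Nanoparticle"))
  if (is.matrix(points)) points <- list(points = points, site = NA,
                                        area = NA, weight = NA)
  pts <- points$points
  if (is.null(pts) || nrow(pts) == 0) stop("no surface points given")
  xyz <- as.matrix(p$sites[, c("x", "y", "z")])
  q <- p$sites$charge
  d <- cross_dist(pts, xyz)
  if (any(d < 1e-9))
    stop("a sample point coincides with a charge site")
  kT <- KBOLTZ * temperature
  if (ionic_strength > 0) {
    n0 <- ionic_strength * 6.02214076e-7
    kappa <- sqrt(8 * pi * KCOUL * n0 / (kT * solvent_dielectric))
    phi_kcal <- (exp(-kappa * d) / d) %*% q * KCOUL / solvent_dielectric
  } else {
    phi_kcal <- (1 / d) %*% q * KCOUL
  }
  structure(list(points = pts, potentials = as.numeric(phi_kcal) / kT,
                 area = (if (is.na(points$area[1])) NA
                         else points$area / 100),      # A^2 -> nm^2
                 total_charge = sum(q),
                 charge_density = (if (is.na(points$area[1])) NA
                                   else sum(q) / (points$area / 100)),
                 site = points$site, temperature = temperature),
            class = "SurfaceMap")
}

#' Classify surface points into charge patches
#'
#' Points are labeled by potential sign outside `+-threshold`; contiguous
#' same-sign patches are the connected components of the point-adjacency
#' graph (edges between points closer than `adjacency`, default twice the
#' mean nearest-neighbor spacing).
#'
#' @param map a `SurfaceMap`
#' @param threshold neutral band half-width \[kBT/e\], default 0
#' @param adjacency adjacency radius \[Angstrom\]; `NULL` = automatic
#' @return list with `labels` (per-point `"positive"`/`"negative"`/
#'   `"neutral"`), `patch` (per-point patch id, `NA` for neutral) and
#'   `patches` (data.frame: id, sign, n_points, mean potential, centroid)
#' @export
classify_patches <- function(map, threshold = 0, adjacency = NULL) {
  stopifnot(inherits(map, "SurfaceMap"))
  if (threshold < 0) stop("threshold must be >= 0")
  phi <- map$potentials
  lab <- ifelse(phi > threshold, "positive",
                ifelse(phi < -threshold, "negative", "neutral"))
  pts <- map$points
  if (is.null(adjacency)) {
    d <- as.matrix(dist(pts))
    diag(d) <- Inf
    adjacency <- 2 * mean(apply(d, 1, min))
  } else {
    d <- as.matrix(dist(pts))
    diag(d) <- Inf
  }
  patch <- rep(NA_integer_, length(phi))
  patches <- list()
  pid <- 0L
  for (sgn in c("positive", "negative")) {
    sel <- which(lab == sgn)
    if (length(sel) == 0) next
    adj <- d[sel, sel, drop = FALSE] <= adjacency
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                             diag = FALSE)
    comp <- igraph::components(g)$membership
    for (cmp in sort(unique(comp))) {
      pid <- pid + 1L
      members <- sel[comp == cmp]
      patch[members] <- pid
      patches[[pid]] <- data.frame(
        id = pid, sign = sgn, n_points = length(members),
        area = length(members) * (if (is.na(map$area[1])) NA
                                  else map$area * 100 / length(phi)),
        mean_potential = mean(phi[members]),
        cx = mean(pts[members, 1]), cy = mean(pts[members, 2]),
        cz = mean(pts[members, 3]))
    }
  }
  list(labels = lab, patch = patch,
       patches = if (pid > 0) do.call(rbind, patches) else
         data.frame(id = integer(0), sign = character(0),
                    n_points = integer(0), area = numeric(0),
                    mean_potential = numeric(0), cx = numeric(0),
                    cy = numeric(0), cz = numeric(0)))
}

#' Geometric surface area of an idealized particle shape
#' @param spec a [particle_spec()]
#' @return area \[nm^2\] of the ideal sphere (`pi d^2`) or capped cylinder
#' @export
particle_geometric_area <- function(spec) {
  stopifnot(inherits(spec, "ParticleSpec"))
  if (spec$shape == "sphere") pi * spec$characteristic_size^2
  else {
    L <- spec$characteristic_size
    W <- L / spec$aspect_ratio
    pi * W * L + 2 * pi * (W / 2)^2
  }
}

#' Charge density across a particle size series
#'
#' Generates each particle and reports its size, geometric surface area,
#' total charge and surface charge density, plus the relative spread of
#' the density across the series (surface-proportional charge patterns
#' keep it nearly constant).
#'
#' @param specs list of [particle_spec()]s of one shape family (>= 2)
#' @return data.frame (size \[nm\], area \[nm^2\], total_charge \[e\],
#'   charge_density \[e/nm^2\]) with attribute `relative_spread` =
#'   (max - min) / mean of the density
#' @export
size_series_density <- function(specs) {
  if (length(specs) < 2)
    stop("a size series needs at least 2 particle specs")
  shapes <- vapply(specs, function(sp) sp$shape, "")
  if (length(unique(shapes)) != 1)
    stop("mixed shapes in size series: ", paste(unique(shapes),
                                                collapse = ", "))
  rows <- lapply(specs, function(sp) {
    part <- make_particle(sp)
    area <- particle_geometric_area(sp)
    data.frame(size = sp$characteristic_size, area = area,
               total_charge = total_charge(part),
               charge_density = total_charge(part) / area)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  dens <- out$charge_density
  attr(out, "relative_spread") <- (max(dens) - min(dens)) / abs(mean(dens))
  out
}
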