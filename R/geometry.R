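#' Low-level constructor for bead-model enzyme geometries
#'
#' A geometry is a set of Lennard-Jones bead centers (nm), a common bead
#' radius, the core sphere(s) the beads decorate, and the index of the bead
#' that acts as the active site.
#'
#' @param centers numeric matrix (n x 3) of bead centers (nm)
#' @param bead_radius bead radius (nm)
#' @param core_radius radius of the core sphere(s) (nm)
#' @param active_site index (1-based) of the active-site bead
#' @param core_centers numeric matrix (m x 3) of core sphere centers
#' @return an object of class `enzyme_geometry`
#' @export
enzyme_geometry <- function(centers, bead_radius, core_radius, active_site,
                            core_centers = matrix(0, 1, 3)) {
  centers <- as.matrix(centers)
  stopifnot(ncol(centers) == 3, bead_radius >= 0,
            active_site >= 1, active_site <= nrow(centers))
  structure(list(centers = centers, bead_radius = bead_radius,
                 core_radius = core_radius,
                 active_site = as.integer(active_site),
                 core_centers = as.matrix(core_centers)),
            class = "enzyme_geometry")
}

#' @export
print.enzyme_geometry <- function(x, ...) {
  cat(sprintf("Bead-model enzyme: %d beads of radius %g nm on %d core sphere(s) of radius %g nm\n",
              nrow(x$centers), x$bead_radius, nrow(x$core_centers),
              x$core_radius))
  cat(sprintf("  active site: bead %d at (%.3f, %.3f, %.3f) nm\n",
              x$active_site, x$centers[x$active_site, 1],
              x$centers[x$active_site, 2], x$centers[x$active_site, 3]))
  invisible(x)
}

# icosahedron vertices on the unit sphere, rotated so vertex 1 sits at +z
icosahedron_vertices <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(1 + phi^2)
  # rotate vertex 1 onto +z so the active site has a canonical position
  a <- v[1, ]
  z <- c(0, 0, 1)
  axis <- c(a[2] * z[3] - a[3] * z[2], a[3] * z[1] - a[1] * z[3],
            a[1] * z[2] - a[2] * z[1])
  s <- sqrt(sum(axis^2)); cth <- sum(a * z)
  if (s < 1e-12) return(v)
  axis <- axis / s
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  Rm <- diag(3) + s * K + (1 - cth) * (K %*% K)
  t(Rm %*% t(v))
}

icosahedron_faces <- function() {
  rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
}

# subdivide an icosphere: each triangle -> 4, midpoints projected on sphere
icosphere <- function(level) {
  v <- icosahedron_vertices()
  f <- icosahedron_faces()
  if (level > 0) {
    for (l in seq_len(level)) {
      mid_cache <- new.env(hash = TRUE)
      midpoint <- function(i, j) {
        key <- paste(min(i, j), max(i, j))
        if (!is.null(mid_cache[[key]])) return(mid_cache[[key]])
        m <- (v[i, ] + v[j, ]) / 2
        m <- m / sqrt(sum(m^2))
        v <<- rbind(v, m)
        idx <- nrow(v)
        mid_cache[[key]] <- idx
        idx
      }
      nf <- matrix(0L, 0, 3)
      for (k in seq_len(nrow(f))) {
        a <- f[k, 1]; b <- f[k, 2]; cc <- f[k, 3]
        ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
        nf <- rbind(nf, c(a, ab, ca), c(b, bc, ab), c(cc, ca, bc),
                    c(ab, bc, ca))
      }
      f <- nf
    }
  }
  list(vertices = v, faces = f)
}

#' Build a triangulated-sphere bead model of an enzyme
#'
#' Beads are placed at the vertices of a subdivided icosahedron projected
#' onto the core sphere (12 beads at level 0, 42 at level 1, 162 at level 2:
#' `10 * 4^level + 2`). The bead at the north pole `(0, 0, core_radius)` is
#' the active site. A warning is issued when neighbouring beads overlap by
#' more than 90 percent of a bead diameter at the chosen level.
#'
#' @param core_radius radius of the core sphere (nm)
#' @param subdivision_level icosphere subdivision level (>= 0)
#' @param bead_radius bead radius (nm)
#' @return an `enzyme_geometry` with the active site on the +z axis
#' @export
build_enzyme <- function(core_radius = 1.5, subdivision_level = 1,
                         bead_radius = 0.37) {
  stopifnot(subdivision_level >= 0, core_radius > 0)
  ico <- icosphere(subdivision_level)
  centers <- ico$vertices * core_radius
  # active site: the vertex closest to +z (vertex 1 was rotated there)
  active <- which.max(centers[, 3])
  d <- as.matrix(stats::dist(centers))
  diag(d) <- Inf
  if (min(d) < 0.1 * 2 * bead_radius)
    warning("beads overlap by more than 90% of a diameter at this subdivision level")
  enzyme_geometry(centers, bead_radius, core_radius, active)
}

#' Merge two enzymes into an enzyme-enzyme complex
#'
#' The second enzyme is placed behind the active site of the first: its core
#' center sits at distance `separation` from the first core center, on the
#' axis through the active site, on the far side. Beads of either enzyme
#' whose centers fall inside the other core sphere are removed (merged
#' spheres). The assembly is recentred at the midpoint of the two cores so
#' that it is as compact as possible with respect to the launch sphere of
#' the rate calculation.
#'
#' @param geom a single-enzyme `enzyme_geometry` from [build_enzyme()]
#' @param separation center-to-center distance of the two cores (nm); values
#'   below one core diameter give merged spheres
#' @return an `enzyme_geometry` of the complex; the active site of the first
#'   enzyme is kept and remains collinear with the two core centers
#' @export
build_complex <- function(geom, separation = 1.4) {
  stopifnot(inherits(geom, "enzyme_geometry"), separation > 0)
  act <- geom$centers[geom$active_site, ]
  axis <- act / sqrt(sum(act^2))          # active site direction (+z)
  c1 <- c(0, 0, 0)
  c2 <- -axis * separation                # second enzyme behind the active site
  beads1 <- geom$centers
  beads2 <- sweep(geom$centers, 2, c2, "+")
  # drop beads swallowed by the other core
  keep1 <- sqrt(rowSums(sweep(beads1, 2, c2, "-")^2)) >= geom$core_radius
  keep2 <- sqrt(rowSums(sweep(beads2, 2, c1, "-")^2)) >= geom$core_radius
  keep1[geom$active_site] <- TRUE         # the active site always survives
  centers <- rbind(beads1[keep1, , drop = FALSE],
                   beads2[keep2, , drop = FALSE])
  active <- sum(keep1[seq_len(geom$active_site)])
  shift <- (c1 + c2) / 2
  centers <- sweep(centers, 2, shift, "-")
  enzyme_geometry(centers, geom$bead_radius, geom$core_radius, active,
                  core_centers = rbind(c1 - shift, c2 - shift))
}

#' Repulsive Lennard-Jones (WCA) energy and force on a substrate bead
#'
#' Sum over all enzyme beads of the repulsive branch of the 12-6 potential:
#' \eqn{4\epsilon[(\sigma/r)^{12} - (\sigma/r)^6] + \epsilon} for
#' \eqn{r \le 2^{1/6}\sigma} and zero beyond, with
#' \eqn{\sigma} = bead radius + substrate radius (the Weeks-Chandler-Andersen
#' split: the potential and force vanish continuously at the minimum). The
#' beads act as soft excluded volume whose stiffness grows with
#' \eqn{\epsilon}; there is no attractive well, so strengthening the
#' interaction can only hinder the approach to the active site. The force
#' is the exact negative gradient.
#'
#' @param pos substrate center, numeric length-3 (nm)
#' @param geom an `enzyme_geometry`
#' @param substrate_radius substrate bead radius (nm)
#' @param eps_lj LJ well depth (units of kT)
#' @return list with `U` (kT) and `F` (length-3, kT/nm)
#' @export
lj_energy_force <- function(pos, geom, substrate_radius = 0.4, eps_lj = 0.1) {
  sigma <- geom$bead_radius + substrate_radius
  rc <- 2^(1 / 6) * sigma
  dx <- sweep(geom$centers, 2, pos, "-") * -1   # pos - center
  r2 <- rowSums(dx^2)
  if (any(r2 == 0)) stop("substrate overlaps a bead center exactly")
  within <- r2 < rc^2
  U <- 0
  F <- c(0, 0, 0)
  if (any(within)) {
    s2 <- sigma^2 / r2[within]
    s6 <- s2^3
    s12 <- s6^2
    U <- sum(4 * eps_lj * (s12 - s6) + eps_lj)
    # dU/dr = 4 eps (-12 s12 + 6 s6)/r ; F = -dU/dr * rhat
    coef <- 4 * eps_lj * (12 * s12 - 6 * s6) / r2[within]
    F <- colSums(dx[within, , drop = FALSE] * coef)
  }
  list(U = U, F = F)
}
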