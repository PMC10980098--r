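#' Deterministic unit-sphere point lattice
#'
#' Golden-spiral (Fibonacci) lattice: a fixed, near-uniform set of points on
#' the unit sphere used to discretise each atom's solvent-accessible sphere.
#' Deterministic by construction, so surface areas need no random seed.
#'
#' @param n number of points (at least 12).
#' @return an `n x 3` matrix of unit vectors.
#' @export
sphere_points <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || n < 12)
    stop_pf("n must be a single integer >= 12", class = "pepforge_bad_npoints")
  n <- as.integer(n)
  i <- seq_len(n)
  z <- 1 - 2 * (i - 0.5) / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- (i - 1) * pi * (3 - sqrt(5))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

as_atom_table <- function(atoms) {
  if (inherits(atoms, "complex_structure")) atoms <- atoms$atoms
  stopifnot(is.data.frame(atoms),
            all(c("x", "y", "z", "radius") %in% names(atoms)))
  if (nrow(atoms) == 0L)
    stop_pf("no atoms supplied", class = "pepforge_bad_atoms")
  if (any(atoms$radius <= 0))
    stop_pf("atom radii must be positive", class = "pepforge_bad_atoms")
  atoms
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Rolls a probe sphere (default 1.4 Angstrom, approximating water) over every
#' atom: each atom's sphere is expanded by the probe radius and sampled with a
#' deterministic point lattice; a sample point is exposed when it falls inside
#' no other expanded sphere. Per-atom area is the exposed fraction of
#' `4*pi*(r+probe)^2`. Neighbour search is pruned by the maximum expanded-radius
#' cutoff, which cannot change the result.
#'
#' @param atoms a `complex_structure` or an atom data frame with columns
#'   `x`, `y`, `z`, `radius`.
#' @param probe_radius solvent probe radius in Angstrom.
#' @param n_points lattice points per atom (accuracy/cost trade-off).
#' @return object of class `sasa_result`: `per_atom_area` (Angstrom^2, input
#'   order) and `total_area`.
#' @export
shrake_rupley <- function(atoms, probe_radius = 1.4, n_points = 960) {
  a <- as_atom_table(atoms)
  stopifnot(probe_radius >= 0)
  pts <- sphere_points(n_points)
  n <- nrow(a)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  R <- a$radius + probe_radius
  # Pairwise center distances once; neighbours of i are atoms whose expanded
  # spheres can intersect i's expanded sphere.
  d2 <- sqdist(xyz, xyz)
  per_atom <- numeric(n)
  for (i in seq_len(n)) {
    cut2 <- (R[i] + R[-i])^2
    nb <- which(d2[i, -i] < cut2)
    nb <- setdiff(seq_len(n)[-i][nb], i)
    if (!length(nb)) {
      per_atom[i] <- 4 * pi * R[i]^2
      next
    }
    p <- pts * R[i]
    p <- sweep(p, 2, xyz[i, ], "+")
    centers <- xyz[nb, , drop = FALSE]
    # squared distance from each lattice point to each neighbour center
    pd2 <- sqdist(p, centers)
    inside <- pd2 < matrix(R[nb]^2, nrow = n_points, ncol = length(nb),
                           byrow = TRUE)
    exposed <- sum(rowSums(inside) == 0L)
    per_atom[i] <- exposed / n_points * 4 * pi * R[i]^2
  }
  structure(list(per_atom_area = per_atom, total_area = sum(per_atom)),
            class = "sasa_result")
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf("<sasa_result> %d atoms, total %.2f A^2\n",
              length(x$per_atom_area), x$total_area))
  invisible(x)
}

#' Interface (buried) surface area of a protein-peptide complex
#'
#' The binding-interface area hidden on complex formation:
#' `SASA(protein alone) + SASA(peptide alone) - SASA(complex)`, all three terms
#' computed with identical Shrake-Rupley parameters on the rigid split (the
#' partner's atoms deleted, coordinates untouched). Small negative values from
#' lattice discretisation are clamped to zero; the raw difference is kept in
#' the `"raw"` attribute.
#'
#' @inheritParams shrake_rupley
#' @param complex a `complex_structure`.
#' @return buried area in Angstrom^2 (non-negative), with attribute `"raw"`.
#' @export
interface_buried_sasa <- function(complex, probe_radius = 1.4,
                                  n_points = 960) {
  validate_complex(complex)
  a <- complex$atoms
  s_complex <- shrake_rupley(a, probe_radius, n_points)$total_area
  s_prot <- shrake_rupley(a[a$role == "protein", , drop = FALSE],
                          probe_radius, n_points)$total_area
  s_pep <- shrake_rupley(a[a$role == "peptide", , drop = FALSE],
                         probe_radius, n_points)$total_area
  raw <- s_prot + s_pep - s_complex
  structure(max(0, raw), raw = raw)
}
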