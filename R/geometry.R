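# Rigid-body superposition, centers of mass, periodic distances and the
# vector geometry shared by the probe suite.

#' Superpose trajectory frames onto a reference
#'
#' Each frame is rigid-body transformed (least-squares rotation with
#' determinant +1, via bio3d's Kabsch implementation) to minimise the RMSD of
#' the fit selection against the reference; the transformation is applied to
#' all atoms of the frame.
#'
#' @param mobile A [trajectory()].
#' @param reference Reference coordinates: `natoms` x 3 matrix or length-3N
#'   vector congruent with the topology.
#' @param fit_selection A [selection()] or atom-index vector (at least 3
#'   atoms) resolving identically on reference and frames.
#' @param top The [topology()] used to resolve `fit_selection`.
#' @return A new [trajectory()] with fitted coordinates.
#' @export
superpose <- function(mobile, reference, fit_selection, top) {
  inds <- resolve_selection(top, fit_selection)
  if (length(inds) < 3) {
    stop(mp_error("selection",
      "superposition needs at least 3 fit atoms, got %d", length(inds)))
  }
  ref <- as_coord_matrix(reference, mobile$natoms)
  ref_vec <- as.vector(t(ref))
  xyz_inds <- bio3d::atom2xyz(inds)
  fitted <- bio3d::fit.xyz(fixed = ref_vec, mobile = mobile$xyz,
                           fixed.inds = xyz_inds, mobile.inds = xyz_inds)
  if (!is.matrix(fitted)) fitted <- matrix(fitted, nrow = 1)
  trajectory(fitted, mobile$box, mobile$time)
}

#' Per-frame RMSD against a reference (no refitting)
#'
#' @param traj A [trajectory()] (typically already superposed).
#' @param reference Reference coordinates (matrix or 3N vector).
#' @param indices Atom indices to measure over.
#' @return Numeric vector, one RMSD (Å) per frame.
#' @export
rmsd_series <- function(traj, reference, indices) {
  ref <- as_coord_matrix(reference, traj$natoms)
  xi <- bio3d::atom2xyz(indices)
  d <- sweep(traj$xyz[, xi, drop = FALSE], 2, as.vector(t(ref))[xi])
  sqrt(rowSums(d^2) / length(indices))
}

#' Center of mass of a selection in one frame
#'
#' @param top A [topology()].
#' @param frame Coordinates, `natoms` x 3 matrix.
#' @param sel A [selection()] or atom indices (must be non-empty).
#' @param weighting `"mass"` (standard atomic masses by element; unknown
#'   elements are an error suggesting geometry weighting) or `"geometry"`
#'   (equal weights).
#' @return Length-3 numeric vector (Å).
#' @export
center_of_mass <- function(top, frame, sel, weighting = c("mass", "geometry")) {
  weighting <- match.arg(weighting)
  inds <- resolve_selection(top, sel)
  w <- if (weighting == "mass") atom_masses(top, inds) else
    rep(1, length(inds))
  colSums(frame[inds, , drop = FALSE] * w) / sum(w)
}

# minimum-image displacement components on an orthorhombic box
min_image <- function(d, box) d - box * round(d / box)

# minimum-image distances from one point to a set of points (n x 3)
pbc_dist <- function(points, origin, box) {
  d <- sweep(points, 2, origin)
  for (k in 1:3) d[, k] <- min_image(d[, k], box[k])
  sqrt(rowSums(d^2))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

unit <- function(v) v / sqrt(sum(v^2))

#' Dihedral angle over trajectory frames
#'
#' Signed torsion (degrees, in (-180, 180]) of four atoms, vectorised over
#' all frames of a trajectory.
#'
#' @param traj A [trajectory()].
#' @param i1,i2,i3,i4 Atom indices defining the torsion.
#' @return Numeric vector, one angle per frame.
#' @export
dihedral_series <- function(traj, i1, i2, i3, i4) {
  p <- lapply(c(i1, i2, i3, i4), function(i) {
    traj$xyz[, bio3d::atom2xyz(i), drop = FALSE]
  })
  b1 <- p[[2]] - p[[1]]
  b2 <- p[[3]] - p[[2]]
  b3 <- p[[4]] - p[[3]]
  cr <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                             a[, 3] * b[, 1] - a[, 1] * b[, 3],
                             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  n1 <- cr(b1, b2)
  n2 <- cr(b2, b3)
  m1 <- cr(n1, b2 / sqrt(rowSums(b2^2)))
  x <- rowSums(n1 * n2)
  y <- rowSums(m1 * n2)
  atan2(y, x) * 180 / pi
}

# rotate points (n x 3) about an axis through `origin` with direction `axis`
# (unit not required) by `angle` degrees, Rodrigues form
rotate_about_axis <- function(points, origin, axis, angle) {
  k <- unit(axis)
  th <- angle * pi / 180
  p <- sweep(points, 2, origin)
  kx <- p[, 1] * k[1] + p[, 2] * k[2] + p[, 3] * k[3]
  crossk <- cbind(k[2] * p[, 3] - k[3] * p[, 2],
                  k[3] * p[, 1] - k[1] * p[, 3],
                  k[1] * p[, 2] - k[2] * p[, 1])
  rot <- p * cos(th) + crossk * sin(th) +
    outer(kx, k) * (1 - cos(th))
  sweep(rot, 2, origin, FUN = "+")
}

# principal axis (first right singular vector) of an n x 3 point set,
# oriented so that it points from the first toward the last point
principal_axis <- function(points) {
  cen <- colMeans(points)
  v <- svd(sweep(points, 2, cen))$v[, 1]
  if (sum(v * (points[nrow(points), ] - points[1, ])) < 0) v <- -v
  unit(v)
}
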