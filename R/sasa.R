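# Shrake-Rupley solvent-accessible surface area. The occluding environment
# is the protein's heavy atoms only; lipids, waters and ions never shadow
# the surface.

# deterministic quasi-uniform unit-sphere points (golden-section spiral)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area of selected residues (Shrake-Rupley)
#'
#' For each heavy atom of the report selection, the fraction of `n_points`
#' quasi-uniform points on the sphere of radius `r_atom + probe` that fall
#' inside no other protein atom's probe-expanded sphere, times
#' 4π(r_atom+probe)². Residue values sum their heavy atoms.
#'
#' @param frame Coordinates, `natoms` x 3 matrix (Å).
#' @param top The [topology()].
#' @param report_selection [selection()] or atom indices whose area is
#'   reported (their residues' heavy atoms are measured).
#' @param probe_radius Solvent probe radius in Å (water: 1.4).
#' @param n_points Sphere points per atom (default 960).
#' @param radii Van der Waals radii by element; unknown atom radius is an
#'   error naming the atom.
#' @return List: `per_atom` (data.frame atom index/area), `per_residue`
#'   (resno/chain/area), `total` (Å², summed over the report selection).
#' @export
sasa <- function(frame, top, report_selection, probe_radius = 1.4,
                 n_points = 960, radii = default_vdw_radii()) {
  env <- heavy_atoms(top, classes = "protein")
  if (length(env) == 0) stop(mp_error("probe", "no protein heavy atoms"))
  rad <- radii[top$atoms$element[env]]
  if (anyNA(rad)) {
    bad <- env[is.na(rad)][1]
    stop(mp_error("probe", "no van der Waals radius for atom %d (%s %s)",
                  top$atoms$eleno[bad], top$atoms$name[bad],
                  top$atoms$element[bad]))
  }
  rep_res <- unique(top$atoms$resind[resolve_selection(top, report_selection)])
  rep_atoms <- env[top$atoms$resind[env] %in% rep_res]
  if (length(rep_atoms) == 0) {
    stop(mp_error("selection", "report selection has no protein heavy atoms"))
  }
  pts <- sphere_points(n_points)
  env_xyz <- frame[env, , drop = FALSE]
  rad_exp <- rad + probe_radius
  area <- vapply(rep_atoms, function(a) {
    pos <- frame[a, ]
    ra <- radii[top$atoms$element[a]] + probe_radius
    # neighbours whose expanded spheres can intersect this atom's shell
    d2 <- (env_xyz[, 1] - pos[1])^2 + (env_xyz[, 2] - pos[2])^2 +
      (env_xyz[, 3] - pos[3])^2
    nb <- which(d2 < (ra + rad_exp)^2 & env != a)
    if (length(nb) == 0) return(4 * pi * ra^2)
    shell <- sweep(pts * ra, 2, pos, FUN = "+")
    free <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(free)) break
      dd <- (shell[free, 1] - env_xyz[j, 1])^2 +
        (shell[free, 2] - env_xyz[j, 2])^2 +
        (shell[free, 3] - env_xyz[j, 3])^2
      free[free] <- dd > rad_exp[j]^2
    }
    4 * pi * ra^2 * mean(free)
  }, numeric(1))
  per_atom <- data.frame(atom = rep_atoms, area = area)
  ri <- top$atoms$resind[rep_atoms]
  per_res <- stats::aggregate(area, list(resind = ri), sum)
  per_residue <- data.frame(resno = top$residues$resno[per_res$resind],
                            chain = top$residues$chain[per_res$resind],
                            area = per_res$x)
  list(per_atom = per_atom, per_residue = per_residue, total = sum(area))
}

#' Per-frame SASA probe series
#'
#' Applies [sasa()] to every frame and reports the summed area of the
#' selection.
#'
#' @inheritParams sasa
#' @param traj A [trajectory()].
#' @param name Probe name (`"sasa_ic"` or `"sasa_t"` select the matching
#'   state threshold).
#' @param thresholds A [default_state_thresholds()] list.
#' @return A [probe_series()] in Å².
#' @export
sasa_series <- function(traj, top, report_selection, name = "sasa",
                        probe_radius = 1.4, n_points = 960,
                        radii = default_vdw_radii(),
                        thresholds = default_state_thresholds()) {
  vals <- vapply(seq_len(traj$nframes), function(f) {
    sasa(traj_frame(traj, f), top, report_selection, probe_radius,
         n_points, radii)$total
  }, numeric(1))
  thr <- switch(name, sasa_ic = thresholds$sasa_ic_cavity_A2,
                sasa_t = thresholds$sasa_t_A2, NULL)
  probe_series(name, vals, "A2", thr, if (is.null(thr)) NULL else ">=",
               traj$time)
}
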