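# Cholesterol occupancy grids, enrichment-based binding-site detection,
# COM occupancy fractions and bound/unbound event traces.

#' Build a 3D lipid occupancy grid
#'
#' Frames are superposed onto the reference over the alignment selection;
#' a voxel counts as occupied in a frame when at least one heavy atom/bead
#' of any molecule of the lipid class falls in it. Occupancy is the
#' fraction of frames occupied. The bulk reference value is the mean
#' occupancy of voxels whose distance from the protein surface lies within
#' the bulk shell, restricted to the membrane slab.
#'
#' @param traj A [trajectory()].
#' @param top The matching [topology()].
#' @param align_selection Fit [selection()] (typically all protein Cα).
#' @param reference Reference coordinates for the alignment.
#' @param voxel Voxel edge length in Å (1.0 for atomistic maps; coarse
#'   fixtures use 2.0).
#' @param bulk_shell Distances (Å) from any protein heavy atom delimiting
#'   the bulk region, default 15-25 Å.
#' @param membrane_halfwidth Half-thickness of the slab around the membrane
#'   midplane (mean lipid z) within which bulk voxels are taken.
#' @param lipid_class Molecule class counted into the grid.
#' @return Object of class `OccupancyGrid`: `origin`, `voxel`, `dim`,
#'   `occupancy` (3D array, fraction of frames), `bulk`, `nframes`,
#'   `reference` (aligned protein coordinates).
#' @export
build_occupancy_grid <- function(traj, top, align_selection,
                                 reference = top$xyz, voxel = 1,
                                 bulk_shell = c(15, 25),
                                 membrane_halfwidth = 15,
                                 lipid_class = "cholesterol-like") {
  lip <- heavy_atoms(top, classes = lipid_class)
  if (length(lip) == 0) {
    stop(mp_error("selection", "no molecules of class '%s'", lipid_class))
  }
  fitted <- superpose(traj, reference, align_selection, top)
  lx <- bio3d::atom2xyz(lip)
  coords <- fitted$xyz[, lx, drop = FALSE]
  xs <- coords[, seq(1, length(lx), 3), drop = FALSE]
  ys <- coords[, seq(2, length(lx), 3), drop = FALSE]
  zs <- coords[, seq(3, length(lx), 3), drop = FALSE]
  origin <- floor(c(min(xs), min(ys), min(zs)) / voxel) * voxel
  dim3 <- ceiling((c(max(xs), max(ys), max(zs)) - origin) / voxel) + 1L
  counts <- array(0L, dim3)
  for (f in seq_len(nrow(coords))) {
    ix <- pmin(floor((xs[f, ] - origin[1]) / voxel) + 1L, dim3[1])
    iy <- pmin(floor((ys[f, ] - origin[2]) / voxel) + 1L, dim3[2])
    iz <- pmin(floor((zs[f, ] - origin[3]) / voxel) + 1L, dim3[3])
    lin <- unique(ix + dim3[1] * (iy - 1L) + dim3[1] * dim3[2] * (iz - 1L))
    counts[lin] <- counts[lin] + 1L
  }
  occ <- counts / traj$nframes
  grid <- structure(list(origin = origin, voxel = voxel, dim = dim3,
                         occupancy = occ, bulk = NA_real_,
                         nframes = traj$nframes, reference = reference),
                    class = "OccupancyGrid")
  grid$bulk <- grid_bulk(grid, top, reference, bulk_shell,
                         membrane_halfwidth, midplane_z = mean(zs))
  grid
}

# voxel centers as an M x 3 matrix for a vector of linear indices
voxel_centers <- function(grid, lin = seq_len(prod(grid$dim))) {
  d <- grid$dim
  i <- (lin - 1L) %% d[1]
  j <- ((lin - 1L) %/% d[1]) %% d[2]
  k <- (lin - 1L) %/% (d[1] * d[2])
  cbind(grid$origin[1] + (i + 0.5) * grid$voxel,
        grid$origin[2] + (j + 0.5) * grid$voxel,
        grid$origin[3] + (k + 0.5) * grid$voxel)
}

# mean occupancy over bulk-shell voxels inside the membrane slab
grid_bulk <- function(grid, top, reference, bulk_shell, membrane_halfwidth,
                      midplane_z) {
  cen <- voxel_centers(grid)
  slab <- abs(cen[, 3] - midplane_z) < membrane_halfwidth
  cand <- which(slab)
  if (length(cand) == 0) stop(mp_error("grid", "empty bulk shell (slab)"))
  prot <- as_coord_matrix(reference, top$natoms)[
    heavy_atoms(top, classes = "protein"), , drop = FALSE]
  dmin <- rep(Inf, length(cand))
  for (chunk in split(seq_len(nrow(prot)),
                      ceiling(seq_len(nrow(prot)) / 256))) {
    p <- prot[chunk, , drop = FALSE]
    d2 <- outer(cen[cand, 1], p[, 1], "-")^2 +
      outer(cen[cand, 2], p[, 2], "-")^2 +
      outer(cen[cand, 3], p[, 3], "-")^2
    dmin <- pmin(dmin, sqrt(apply(d2, 1, min)))
  }
  keep <- cand[dmin >= bulk_shell[1] & dmin <= bulk_shell[2]]
  if (length(keep) == 0) {
    stop(mp_error("grid", "empty bulk shell %g-%g A", bulk_shell[1],
                  bulk_shell[2]))
  }
  mean(grid$occupancy[keep])
}

#' Detect lipid binding sites from an occupancy grid
#'
#' Voxels with occupancy at least `enrichment` times the bulk value are
#' thresholded and grouped into 6-connected (face-adjacent) components; each
#' component becomes a binding site with an occupancy-weighted centroid,
#' peak enrichment, and the protein residues having any heavy atom within
#' `contact` Å of any member voxel center. Sites are sorted by decreasing
#' peak enrichment.
#'
#' @param grid An [build_occupancy_grid()] result; `grid$bulk` must be > 0.
#' @param top The [topology()].
#' @param reference Protein reference coordinates (same alignment frame as
#'   the grid); defaults to the grid's.
#' @param enrichment Occupancy-over-bulk threshold (default 3).
#' @param contact Residue contact distance in Å (default 6).
#' @return List of `BindingSite` objects: `id`, `centroid`, `resno`,
#'   `chain`, `voxels` (M x 3 centers), `peak_enrichment`.
#' @export
detect_sites <- function(grid, top, reference = grid$reference,
                         enrichment = 3, contact = 6) {
  if (!is.finite(grid$bulk) || grid$bulk <= 0) {
    stop(mp_error("grid", paste0(
      "bulk occupancy is zero; sample more frames or more lipids before ",
      "calling sites")))
  }
  thr <- enrichment * grid$bulk
  hot <- which(grid$occupancy >= thr)
  if (length(hot) == 0) return(list())
  d <- grid$dim
  lab <- 0L
  hotset <- new.env(hash = TRUE, parent = emptyenv())
  for (h in hot) assign(as.character(h), NA_integer_, envir = hotset)
  offsets <- c(1L, -1L, d[1], -d[1], d[1] * d[2], -d[1] * d[2])
  coord_of <- function(lin) c((lin - 1L) %% d[1],
                              ((lin - 1L) %/% d[1]) %% d[2],
                              (lin - 1L) %/% (d[1] * d[2]))
  for (h in hot) {
    if (!is.na(get(as.character(h), envir = hotset))) next
    lab <- lab + 1L
    queue <- h
    assign(as.character(h), lab, envir = hotset)
    while (length(queue) > 0) {
      v <- queue[1]
      queue <- queue[-1]
      cv <- coord_of(v)
      for (o in seq_along(offsets)) {
        nbr <- v + offsets[o]
        cn <- cv + switch(o, c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                          c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
        if (any(cn < 0) || any(cn >= d)) next
        key <- as.character(nbr)
        if (exists(key, envir = hotset) &&
            is.na(get(key, envir = hotset))) {
          assign(key, lab, envir = hotset)
          queue <- c(queue, nbr)
        }
      }
    }
  }
  labels <- vapply(as.character(hot), get, integer(1), envir = hotset)
  prot <- as_coord_matrix(reference, top$natoms)
  prot_heavy <- heavy_atoms(top, classes = "protein")
  sites <- lapply(seq_len(lab), function(l) {
    lin <- hot[labels == l]
    cen <- voxel_centers(grid, lin)
    w <- grid$occupancy[lin]
    centroid <- colSums(cen * w) / sum(w)
    # residues in contact with any member voxel center
    near <- vapply(prot_heavy, function(a) {
      min(sqrt((cen[, 1] - prot[a, 1])^2 + (cen[, 2] - prot[a, 2])^2 +
                 (cen[, 3] - prot[a, 3])^2)) <= contact
    }, logical(1))
    ri <- unique(top$atoms$resind[prot_heavy[near]])
    structure(list(id = l, centroid = centroid,
                   resno = top$residues$resno[ri],
                   chain = top$residues$chain[ri],
                   voxels = cen, peak_enrichment = max(w) / grid$bulk),
              class = "BindingSite")
  })
  ord <- order(vapply(sites, function(s) s$peak_enrichment, numeric(1)),
               decreasing = TRUE)
  sites <- sites[ord]
  for (i in seq_along(sites)) sites[[i]]$id <- i
  sites
}

#' @export
print.BindingSite <- function(x, ...) {
  cat(sprintf(
    "BindingSite %d: centroid (%.1f, %.1f, %.1f), %d voxel(s), peak %.1fx bulk\n  residues: %s\n",
    x$id, x$centroid[1], x$centroid[2], x$centroid[3], nrow(x$voxels),
    x$peak_enrichment, paste(sort(x$resno), collapse = ", ")))
  invisible(x)
}

# mass-weighted COM series (frames x 3) of a set of atom indices
com_series <- function(traj, top, indices, weighting = "mass") {
  w <- if (weighting == "mass") atom_masses(top, indices) else
    rep(1, length(indices))
  xi <- bio3d::atom2xyz(indices)
  x <- traj$xyz[, xi[seq(1, length(xi), 3)], drop = FALSE]
  y <- traj$xyz[, xi[seq(2, length(xi), 3)], drop = FALSE]
  z <- traj$xyz[, xi[seq(3, length(xi), 3)], drop = FALSE]
  cbind(as.vector(x %*% w), as.vector(y %*% w), as.vector(z %*% w)) / sum(w)
}

# residue indices (into the residue table) of a lipid class
lipid_residues <- function(top, lipid_class = "cholesterol-like") {
  which(top$residues$class == lipid_class)
}

#' Site occupancy fraction (COM rule)
#'
#' Fraction of frames in which the center of mass of at least one
#' cholesterol-class molecule lies within `cutoff` Å (strict) of the center
#' of mass of the site residues (both mass-weighted over heavy atoms).
#'
#' @param traj A [trajectory()].
#' @param top The [topology()].
#' @param site A `BindingSite` from [detect_sites()], or an integer vector
#'   of site residue numbers.
#' @param cutoff COM-COM cutoff in Å (default 8).
#' @param lipid_class Molecule class tested against the site.
#' @return Fraction in \[0, 1\].
#' @export
site_occupancy_fraction <- function(traj, top, site, cutoff = 8,
                                    lipid_class = "cholesterol-like") {
  resno <- if (inherits(site, "BindingSite")) site$resno else site
  site_atoms <- heavy_atoms(
    top, indices = which(top$atoms$resno %in% resno &
                           top$residues$class[top$atoms$resind] == "protein"))
  if (length(site_atoms) == 0) {
    stop(mp_error("selection", "site residues resolve to no protein atom"))
  }
  lres <- lipid_residues(top, lipid_class)
  if (length(lres) == 0) {
    stop(mp_error("selection", "no molecules of class '%s'", lipid_class))
  }
  site_com <- com_series(traj, top, site_atoms)
  occupied <- rep(FALSE, traj$nframes)
  for (r in lres) {
    mol <- heavy_atoms(top, indices = which(top$atoms$resind == r))
    mcom <- com_series(traj, top, mol)
    d <- mcom - site_com
    for (k in 1:3) d[, k] <- min_image(d[, k], traj$box[, k])
    occupied <- occupied | sqrt(rowSums(d^2)) < cutoff
  }
  mean(occupied)
}

#' Bound/unbound trace of one cholesterol molecule at a site
#'
#' Per-frame COM separation between the molecule and the site residues; the
#' molecule is bound when the distance is strictly below the cutoff. No
#' smoothing is applied.
#'
#' @inheritParams site_occupancy_fraction
#' @param molecule Residue number (with optional `chain=`) of the
#'   cholesterol molecule, or its index in the residue table.
#' @param chain Chain of the molecule, `NA` for any.
#' @param cutoff Bound cutoff in Å (default 5).
#' @return Object of class `BoundTrace`: `molecule`, `site_id`,
#'   `distances`, `bound`, `cutoff`, `time`.
#' @export
bound_trace <- function(traj, top, molecule, site, cutoff = 5, chain = NA,
                        lipid_class = "cholesterol-like") {
  res <- top$residues
  ri <- which(res$resno == molecule &
                (is.na(chain) | res$chain == chain) &
                res$class == lipid_class)
  if (length(ri) != 1) {
    stop(mp_error("selection",
      "molecule %s is not a unique molecule of class '%s'", molecule,
      lipid_class))
  }
  resno <- if (inherits(site, "BindingSite")) site$resno else site
  site_atoms <- heavy_atoms(
    top, indices = which(top$atoms$resno %in% resno &
                           top$residues$class[top$atoms$resind] == "protein"))
  mol <- heavy_atoms(top, indices = which(top$atoms$resind == ri))
  d <- com_series(traj, top, mol) - com_series(traj, top, site_atoms)
  for (k in 1:3) d[, k] <- min_image(d[, k], traj$box[, k])
  dist <- sqrt(rowSums(d^2))
  structure(list(molecule = molecule,
                 site_id = if (inherits(site, "BindingSite")) site$id else NA,
                 distances = dist, bound = dist < cutoff, cutoff = cutoff,
                 time = traj$time),
            class = "BoundTrace")
}

#' Count binding/unbinding events and dwell times
#'
#' A binding event is an unbound-to-bound transition, an unbinding event the
#' reverse; dwell times are the durations of consecutive bound runs (frame
#' spacing from the trace time stamps).
#'
#' @param trace A [bound_trace()] result (non-empty).
#' @return List: `n_binding`, `n_unbinding`, `dwell_times` (same time units
#'   as the trace).
#' @export
count_binding_events <- function(trace) {
  b <- trace$bound
  if (length(b) == 0) stop(mp_error("probe", "empty trace"))
  dt <- if (length(trace$time) > 1) diff(trace$time)[1] else 1
  runs <- rle(b)
  trans <- diff(as.integer(b))
  list(n_binding = sum(trans == 1),
       n_unbinding = sum(trans == -1),
       dwell_times = runs$lengths[runs$values] * dt)
}

#' Write an occupancy grid in OpenDX volumetric format
#'
#' @param grid An [build_occupancy_grid()] result.
#' @param path Output path (conventionally `.dx`).
#' @return `path`, invisibly.
#' @export
write_dx <- function(grid, path) {
  d <- grid$dim
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.4f %.4f %.4f", grid$origin[1] + grid$voxel / 2,
            grid$origin[2] + grid$voxel / 2, grid$origin[3] + grid$voxel / 2),
    sprintf("delta %.4f 0 0", grid$voxel),
    sprintf("delta 0 %.4f 0", grid$voxel),
    sprintf("delta 0 0 %.4f", grid$voxel),
    sprintf("object 2 class gridconnections counts %d %d %d",
            d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(d))), con)
  # DX order: x slowest, z fastest
  flat <- as.vector(aperm(grid$occupancy, c(3, 2, 1)))
  pad <- (-length(flat)) %% 3
  flat <- c(flat, rep(NA, pad))
  m <- matrix(flat, ncol = 3, byrow = TRUE)
  lines <- apply(m, 1, function(r) paste(sprintf("%.6g", r[!is.na(r)]),
                                         collapse = " "))
  writeLines(lines, con)
  writeLines(c('attribute "dep" string "positions"',
               'object "density" class field',
               'component "positions" value 1',
               'component "connections" value 2',
               'component "data" value 3'), con)
  invisible(path)
}
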