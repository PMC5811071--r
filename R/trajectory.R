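#' Construct a Trajectory
#'
#' A `Trajectory` is a stack of coordinate frames congruent with a
#' [topology()]: an `nframes x 3*natoms` coordinate matrix (Å, bio3d xyz
#' layout), per-frame orthorhombic box lengths (Å) and frame time stamps
#' (ns).
#'
#' @param xyz Numeric matrix, `nframes x 3*natoms`.
#' @param box Per-frame box lengths: `nframes x 3` matrix or length-3 vector
#'   (recycled to all frames). Must be strictly positive.
#' @param time Frame time stamps in ns, non-decreasing. Default `0:(F-1)`.
#' @return Object of class `Trajectory` with elements `xyz`, `box`, `time`,
#'   `nframes`, `natoms`.
#' @export
trajectory <- function(xyz, box, time = NULL) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) %% 3 != 0) {
    stop(mp_error("shape", "xyz column count %d is not a multiple of 3",
                  ncol(xyz)))
  }
  nf <- nrow(xyz)
  if (!is.matrix(box)) box <- matrix(box, nrow = nf, ncol = 3, byrow = TRUE)
  if (nrow(box) != nf || ncol(box) != 3) {
    stop(mp_error("shape", "box must be %d x 3", nf))
  }
  if (any(!is.finite(box)) || any(box <= 0)) {
    stop(mp_error("format", "box lengths must be strictly positive"))
  }
  if (is.null(time)) time <- as.numeric(seq_len(nf) - 1L)
  if (length(time) != nf || any(diff(time) < 0)) {
    stop(mp_error("format", "time stamps must have one non-decreasing value per frame"))
  }
  structure(list(xyz = unname(xyz), box = unname(box), time = time,
                 nframes = nf, natoms = ncol(xyz) %/% 3L),
            class = "Trajectory")
}

#' @export
print.Trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d frames x %d atoms, t = %.6g..%.6g ns\n",
              x$nframes, x$natoms, x$time[1], x$time[x$nframes]))
  invisible(x)
}

#' Extract one frame as an N x 3 coordinate matrix
#' @param traj A [trajectory()].
#' @param i Frame index (1-based).
#' @return `natoms` x 3 matrix (Å).
#' @export
traj_frame <- function(traj, i) {
  if (i < 1 || i > traj$nframes) {
    stop(mp_error("index", "frame %d out of range 1..%d", i, traj$nframes))
  }
  matrix(traj$xyz[i, ], ncol = 3, byrow = TRUE)
}

#' Read a trajectory congruent with a topology
#'
#' Multi-model PDB is the reference format (`MODEL`/`ENDMDL` blocks, one
#' frame each; a single-model file yields a one-frame trajectory). The box
#' is taken from `CRYST1` records: one per model if present, otherwise the
#' single record is replicated to all frames. DCD files are read through
#' bio3d where the extension is `.dcd`.
#'
#' @param path File path.
#' @param top The matching [topology()]; frame atom counts must agree.
#' @param dt Frame spacing in ns used to synthesise time stamps (PDB and
#'   DCD carry no usable time axis here); default 1 frame = `dt` ns.
#' @param default_box Box lengths used when the file has no `CRYST1` record.
#' @return A [trajectory()].
#' @export
read_trajectory <- function(path, top, dt = 1,
                            default_box = c(100, 100, 100)) {
  if (!file.exists(path)) stop(mp_error("io", "file not found: %s", path))
  if (grepl("\\.dcd$", path, ignore.case = TRUE)) {
    xyz <- tryCatch(bio3d::read.dcd(path, verbose = FALSE),
                    error = function(e) stop(mp_error("format",
                      "cannot parse DCD '%s': %s", path, conditionMessage(e))))
    boxes <- matrix(default_box, nrow(xyz), 3, byrow = TRUE)
  } else {
    parsed <- parse_multimodel_pdb(path)
    xyz <- parsed$xyz
    boxes <- parsed$box
    if (is.null(boxes)) boxes <- matrix(default_box, nrow(xyz), 3, byrow = TRUE)
  }
  if (ncol(xyz) != 3 * top$natoms) {
    stop(mp_error("shape",
      "trajectory atom count %d does not match topology atom count %d",
      ncol(xyz) %/% 3L, top$natoms))
  }
  trajectory(xyz, boxes, time = dt * (seq_len(nrow(xyz)) - 1))
}

# internal multi-model reader: bio3d handles the records; this wrapper adds
# per-model CRYST1 capture and the truncated-final-frame contract.
parse_multimodel_pdb <- function(path) {
  lines <- readLines(path)
  cryst <- grep("^CRYST1", lines)
  model_starts <- grep("^MODEL", lines)
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  if (length(model_starts) > 1) {
    # per-model atom counts must be congruent; a short final block means a
    # truncated frame and is reported by index, not silently dropped
    counts <- vapply(seq_along(model_starts), function(i) {
      to <- if (i < length(model_starts)) model_starts[i + 1] else length(lines)
      sum(is_atom[model_starts[i]:to])
    }, integer(1))
    if (length(unique(counts)) != 1) {
      stop(mp_error("format",
        "truncated trajectory: frame %d of '%s' has %d atoms, expected %d",
        which(counts != counts[1])[1], path,
        counts[counts != counts[1]][1], counts[1]))
    }
  }
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                  error = function(e) stop(mp_error("format",
                    "cannot parse PDB '%s': %s", path, conditionMessage(e))))
  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  if (anyNA(xyz)) {
    stop(mp_error("format", "trajectory '%s' contains unreadable coordinates",
                  path))
  }
  box <- NULL
  if (length(cryst) > 0) {
    bx <- t(vapply(lines[cryst], function(l) {
      as.numeric(c(substr(l, 7, 15), substr(l, 16, 24), substr(l, 25, 33)))
    }, numeric(3)))
    box <- if (nrow(bx) == nrow(xyz)) bx else
      matrix(bx[1, ], nrow(xyz), 3, byrow = TRUE)
  }
  list(xyz = xyz, box = box)
}

#' Write a trajectory as a multi-model PDB
#'
#' One `MODEL`/`ENDMDL` block per frame preceded by a `CRYST1` record
#' (first-frame box; PDB stores a single cell). Coordinates are written at
#' the format precision of 0.001 Å. Output is byte-deterministic.
#'
#' @param traj A [trajectory()].
#' @param top The matching [topology()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_pdb <- function(traj, top, path) {
  if (traj$natoms != top$natoms) {
    stop(mp_error("shape", "trajectory/topology atom counts differ"))
  }
  at <- top$atoms
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                     traj$box[1, 1], traj$box[1, 2], traj$box[1, 3],
                     90, 90, 90), con)
  name4 <- ifelse(nchar(at$name) < 4, sprintf(" %-3s", at$name),
                  sprintf("%-4s", at$name))
  pre <- sprintf("ATOM  %5d %s %-4s%1s%4d    ",
                 (at$eleno - 1L) %% 99999L + 1L, name4,
                 substr(at$resid, 1, 4), substr(at$chain, 1, 1), at$resno)
  post <- sprintf("  1.00  0.00          %2s", at$element)
  for (f in seq_len(traj$nframes)) {
    co <- traj_frame(traj, f)
    writeLines(sprintf("MODEL     %4d", f), con)
    writeLines(paste0(pre, sprintf("%8.3f%8.3f%8.3f", co[, 1], co[, 2],
                                   co[, 3]), post), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
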