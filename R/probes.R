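# The six-probe transition metric suite: TM5 RMSD, TM5 helicity, TM5 kink
# angle, Na2-site water count, IC exit-path SASA and single-threonine SASA,
# plus per-residue RMSF, gate-distance monitors and the inward-state caller.

#' Construct a ProbeSeries
#'
#' Per-frame values of one named metric, with the threshold the inward-state
#' caller compares it against.
#'
#' @param name Probe name (e.g. `"tm5_rmsd"`).
#' @param values Numeric vector, one finite value per frame.
#' @param units Unit string fixed per probe name (e.g. `"A"`, `"%"`).
#' @param threshold Threshold value or `NULL`.
#' @param direction `">="` or `"<="`: the side of the threshold that marks
#'   the inward-facing state.
#' @param time Optional frame time stamps (ns).
#' @return Object of class `ProbeSeries`.
#' @export
probe_series <- function(name, values, units, threshold = NULL,
                         direction = NULL, time = NULL) {
  if (any(!is.finite(values))) {
    stop(mp_error("probe", "probe '%s' produced non-finite values", name))
  }
  structure(list(name = name, values = as.numeric(values), units = units,
                 threshold = threshold, direction = direction,
                 time = time %||% (seq_along(values) - 1)),
            class = "ProbeSeries")
}

#' @export
print.ProbeSeries <- function(x, ...) {
  thr <- if (is.null(x$threshold)) "" else
    sprintf(" [inward: %s %g %s]", x$direction, x$threshold, x$units)
  cat(sprintf("ProbeSeries '%s': %d frames, range %.3g..%.3g %s%s\n",
              x$name, length(x$values), min(x$values), max(x$values),
              x$units, thr))
  invisible(x)
}

#' Inward-state thresholds of the six-probe suite
#'
#' The dashed-line values of the inward-occluded reference state: TM5 RMSD
#' 5 Å, TM5 helicity 50%, kink angle 20°, 15 waters at the Na2 site, 220 Å²
#' for the IC exit-path SASA and 50 Å² for the threonine SASA.
#'
#' @return Named list of class `StateThresholds`.
#' @export
default_state_thresholds <- function() {
  structure(list(tm5_rmsd_A = 5, helicity_pct = 50, kink_deg = 20,
                 n_water = 15, sasa_ic_cavity_A2 = 220, sasa_t_A2 = 50),
            class = "StateThresholds")
}

# protein C-alpha atom indices, optionally keeping/excluding residue numbers
protein_ca <- function(top, keep_resno = NULL, drop_resno = NULL) {
  at <- top$atoms
  cls <- top$residues$class[at$resind]
  keep <- at$name == "CA" & cls == "protein"
  if (!is.null(keep_resno)) keep <- keep & at$resno %in% keep_resno
  if (!is.null(drop_resno)) keep <- keep & !(at$resno %in% drop_resno)
  which(keep)
}

#' TM5 RMSD probe
#'
#' Per frame: superpose on the protein core (all protein Cα except the
#' core-fit exclusions: termini, TM5 and EC loop 2), then compute the Cα
#' RMSD of the IC half of TM5 against the reference without refitting.
#'
#' @param traj A [trajectory()].
#' @param top The matching [topology()].
#' @param presets A [load_selection_presets()] object.
#' @param reference Reference coordinates; default the topology's.
#' @param thresholds A [default_state_thresholds()] list.
#' @return A [probe_series()] in Å.
#' @export
tm5_rmsd <- function(traj, top, presets, reference = top$xyz,
                     thresholds = default_state_thresholds()) {
  fit <- protein_ca(top, drop_resno = presets$core_fit_exclusions)
  if (length(fit) == 0) {
    stop(mp_error("selection", "core fit set is empty after exclusions"))
  }
  fitted <- superpose(traj, reference, fit, top)
  tm5 <- protein_ca(top, keep_resno = presets$tm5_ic_half)
  if (length(tm5) == 0) {
    stop(mp_error("selection",
      "no C-alpha atoms in the TM5 window %d-%d of this topology",
      min(presets$tm5_ic_half), max(presets$tm5_ic_half)))
  }
  probe_series("tm5_rmsd", rmsd_series(fitted, reference, tm5), "A",
               thresholds$tm5_rmsd_A, ">=", traj$time)
}

#' Per-residue Cα RMSF
#'
#' Frames are superposed onto the reference over the fit selection; the RMSF
#' of each Cα is the root-mean-square deviation from its time-averaged
#' position.
#'
#' @inheritParams tm5_rmsd
#' @param fit_selection Fit [selection()] or atom indices.
#' @return data.frame with `resno`, `chain`, `rmsf` (Å).
#' @export
per_residue_rmsf <- function(traj, top, fit_selection, reference = top$xyz) {
  if (traj$nframes < 2) {
    stop(mp_error("probe", "RMSF needs at least 2 frames"))
  }
  fitted <- superpose(traj, reference, fit_selection, top)
  ca <- protein_ca(top)
  xi <- bio3d::atom2xyz(ca)
  x <- fitted$xyz[, xi, drop = FALSE]
  dev <- sweep(x, 2, colMeans(x))
  msd3 <- matrix(colMeans(dev^2), ncol = 3, byrow = TRUE)
  data.frame(resno = top$atoms$resno[ca], chain = top$atoms$chain[ca],
             rmsf = sqrt(rowSums(msd3)))
}

#' TM5 helicity probe (percent α-helical residues)
#'
#' A residue is α-helical when its backbone dihedrals fall in the window
#' φ ∈ \[-100°, -30°\] and ψ ∈ \[-67°, -7°\]. Terminal residues lacking a
#' dihedral (no preceding C or following N in the chain) are excluded from
#' the denominator.
#'
#' @inheritParams tm5_rmsd
#' @param segment Integer vector of residue numbers (contiguous range with
#'   backbone N, CA, C present).
#' @param chain Chain id or `NA` for any.
#' @param phi_window,psi_window Dihedral windows in degrees.
#' @return A [probe_series()] in percent (0-100).
#' @export
helicity <- function(traj, top, segment, chain = NA,
                     phi_window = c(-100, -30), psi_window = c(-67, -7),
                     thresholds = default_state_thresholds()) {
  at <- top$atoms
  in_chain <- if (is.na(chain)) rep(TRUE, nrow(at)) else at$chain == chain
  bb_index <- function(resno, name) {
    i <- which(in_chain & at$resno == resno & at$name == name)
    if (length(i) == 0) NA_integer_ else i[1]
  }
  need <- expand.grid(resno = segment, name = c("N", "CA", "C"),
                      stringsAsFactors = FALSE)
  have <- mapply(bb_index, need$resno, need$name)
  if (anyNA(have)) {
    stop(mp_error("probe", "missing backbone atoms for residue(s): %s",
                  paste(unique(need$resno[is.na(have)]), collapse = ", ")))
  }
  helical <- matrix(NA, nrow = traj$nframes, ncol = length(segment))
  counted <- logical(length(segment))
  for (j in seq_along(segment)) {
    r <- segment[j]
    iN <- bb_index(r, "N"); iCA <- bb_index(r, "CA"); iC <- bb_index(r, "C")
    iCprev <- bb_index(r - 1, "C")
    iNnext <- bb_index(r + 1, "N")
    if (is.na(iCprev) || is.na(iNnext)) next
    counted[j] <- TRUE
    phi <- dihedral_series(traj, iCprev, iN, iCA, iC)
    psi <- dihedral_series(traj, iN, iCA, iC, iNnext)
    helical[, j] <- phi >= phi_window[1] & phi <= phi_window[2] &
      psi >= psi_window[1] & psi <= psi_window[2]
  }
  if (!any(counted)) {
    stop(mp_error("probe", "no residue of the segment has both dihedrals"))
  }
  pct <- 100 * rowMeans(helical[, counted, drop = FALSE])
  probe_series("helicity", pct, "%", thresholds$helicity_pct, "<=",
               traj$time)
}

#' TM5 kink-angle probe
#'
#' Fits a principal axis (first singular vector of the centred Cα
#' coordinates) to the sub-segments preceding and following the hinge
#' residue (hinge ±1 excluded), orients both N→C, and reports the angle
#' between them in \[0°, 180°\] (0 = collinear, no wrap).
#'
#' @inheritParams helicity
#' @param hinge Hinge residue number (e.g. the TM5 proline).
#' @return Object of class `KinkResult`: list with `series` (a
#'   [probe_series()] in degrees), `axis_pre`, `axis_post` (F x 3 unit
#'   vectors) and `hinge`.
#' @export
kink_angle <- function(traj, top, segment, hinge, chain = NA,
                       thresholds = default_state_thresholds()) {
  pre_res <- segment[segment <= hinge - 2]
  post_res <- segment[segment >= hinge + 2]
  if (length(pre_res) < 4 || length(post_res) < 4) {
    stop(mp_error("probe",
      "need >= 4 C-alpha on each side of hinge %d (have %d and %d)",
      hinge, length(pre_res), length(post_res)))
  }
  ca_pre <- protein_ca(top, keep_resno = pre_res)
  ca_post <- protein_ca(top, keep_resno = post_res)
  F <- traj$nframes
  theta <- numeric(F)
  ax1 <- ax2 <- matrix(0, F, 3)
  for (f in seq_len(F)) {
    co <- traj_frame(traj, f)
    a1 <- principal_axis(co[ca_pre, , drop = FALSE])
    a2 <- principal_axis(co[ca_post, , drop = FALSE])
    ax1[f, ] <- a1
    ax2[f, ] <- a2
    theta[f] <- acos(pmin(1, pmax(-1, sum(a1 * a2)))) * 180 / pi
  }
  structure(list(series = probe_series("kink", theta, "deg",
                                       thresholds$kink_deg, ">=", traj$time),
                 axis_pre = ax1, axis_post = ax2, hinge = hinge),
            class = "KinkResult")
}

#' Na2-site water-count probe
#'
#' Number of distinct water molecules whose oxygen lies within the cutoff of
#' the instantaneous geometric center of the Na2-site residues' heavy atoms
#' (minimum-image distances on the frame box).
#'
#' @inheritParams tm5_rmsd
#' @param na2_site [selection()] of the Na2-coordinating residues.
#' @param cutoff Distance cutoff in Å.
#' @return A [probe_series()] (count per frame).
#' @export
water_count <- function(traj, top, na2_site, cutoff = 10,
                        thresholds = default_state_thresholds()) {
  wat_res <- which(top$residues$class == "water")
  if (length(wat_res) == 0) {
    return(probe_series("water", rep(0, traj$nframes), "count",
                        thresholds$n_water, ">=", traj$time))
  }
  is_wat <- top$atoms$resind %in% wat_res
  ox <- which(is_wat & top$atoms$element == "O")
  lack <- setdiff(wat_res, unique(top$atoms$resind[ox]))
  if (length(lack) > 0) {
    stop(mp_error("probe", "%d water residue(s) lack an oxygen atom",
                  length(lack)))
  }
  site <- heavy_atoms(top, indices = resolve_selection(top, na2_site))
  counts <- vapply(seq_len(traj$nframes), function(f) {
    co <- traj_frame(traj, f)
    com <- colMeans(co[site, , drop = FALSE])
    sum(pbc_dist(co[ox, , drop = FALSE], com, traj$box[f, ]) < cutoff)
  }, numeric(1))
  probe_series("water", counts, "count", thresholds$n_water, ">=",
               traj$time)
}

# side-chain contact atom names per contact role
.contact_atoms <- list(
  basic_N = list(ARG = c("NE", "NH1", "NH2"), LYS = "NZ",
                 HIS = c("ND1", "NE2"), HSD = c("ND1", "NE2"),
                 HSE = c("ND1", "NE2"), HSP = c("ND1", "NE2")),
  acidic_O = list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2")),
  ring = list(PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
              TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
              TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2",
                      "CZ3", "CH2"),
              HIS = c("CG", "ND1", "CD2", "CE1", "NE2")),
  hydroxyl_O = list(SER = "OG", THR = "OG1", TYR = "OH"))

contact_indices <- function(top, resno, role, chain = NA) {
  at <- top$atoms
  keep <- at$resno == resno
  if (!is.na(chain)) keep <- keep & at$chain == chain
  rname <- unique(at$resid[keep])
  if (length(rname) != 1) {
    stop(mp_error("selection", "residue %s ambiguous or absent", resno))
  }
  names <- .contact_atoms[[role]][[rname]]
  if (is.null(names)) {
    stop(mp_error("probe",
      "residue %s (%s) is incompatible with contact role '%s'",
      resno, rname, role))
  }
  i <- which(keep & at$name %in% names)
  if (length(i) == 0) {
    stop(mp_error("probe", "residue %s (%s) lacks %s atoms (%s)",
                  resno, rname, role, paste(names, collapse = ",")))
  }
  i
}

#' Gate-distance monitors
#'
#' Per-frame contact distances for gate residue pairs. Salt-bridge pairs
#' report the minimum distance between basic side-chain nitrogens and acidic
#' carboxylate oxygens; aromatic pairs the distance between ring heavy-atom
#' centroids; polar pairs the minimum hydroxyl-O to carboxylate-O distance.
#' Raw distances are reported; any contact cutoff is left to presentation.
#'
#' @inheritParams tm5_rmsd
#' @param pairs data.frame with columns `label`, `a`, `b` (residue numbers)
#'   and `type` (`"salt_bridge"`, `"aromatic"`, `"polar"`), e.g. the
#'   `gates` element of [load_selection_presets()].
#' @param chain Chain id or `NA` for any.
#' @return List of `GateTrace` objects (label, per-frame `distances` in Å,
#'   `type`).
#' @export
gate_distances <- function(traj, top, pairs, chain = NA) {
  roles <- list(salt_bridge = c("basic_N", "acidic_O"),
                aromatic = c("ring", "ring"),
                polar = c("hydroxyl_O", "acidic_O"))
  lapply(seq_len(nrow(pairs)), function(k) {
    p <- pairs[k, ]
    role <- roles[[p$type]]
    if (is.null(role)) {
      stop(mp_error("probe", "unknown contact type '%s'", p$type))
    }
    if (p$type == "aromatic") {
      ia <- contact_indices(top, p$a, "ring", chain)
      ib <- contact_indices(top, p$b, "ring", chain)
    } else {
      # asymmetric roles: accept the pair in either residue order
      first <- tryCatch(list(contact_indices(top, p$a, role[1], chain),
                             contact_indices(top, p$b, role[2], chain)),
                        error = function(e) NULL)
      if (is.null(first)) {
        first <- list(contact_indices(top, p$b, role[1], chain),
                      contact_indices(top, p$a, role[2], chain))
      }
      ia <- first[[1]]
      ib <- first[[2]]
    }
    d <- vapply(seq_len(traj$nframes), function(f) {
      co <- traj_frame(traj, f)
      A <- co[ia, , drop = FALSE]
      B <- co[ib, , drop = FALSE]
      if (p$type == "aromatic") {
        sqrt(sum((colMeans(A) - colMeans(B))^2))
      } else {
        min(vapply(seq_len(nrow(A)), function(i) {
          min(pbc_dist(B, A[i, ], traj$box[f, ]))
        }, numeric(1)))
      }
    }, numeric(1))
    structure(list(label = p$label, distances = d, type = p$type,
                   time = traj$time),
              class = "GateTrace")
  })
}

#' Call the inward-occluded state from the six probes
#'
#' A frame satisfies a probe when its value lies on the inward side of the
#' threshold, inclusively (RMSD ≥, helicity ≤, kink ≥, water ≥, both SASA
#' ≥). A trajectory "shows transition" when at least one frame satisfies
#' all six.
#'
#' @param probes Named list of six [probe_series()]: `tm5_rmsd`, `helicity`,
#'   `kink`, `water`, `sasa_ic`, `sasa_t`.
#' @param thresholds A [default_state_thresholds()] list.
#' @return List: `flags` (frames x 6 logical matrix), `all_six` (logical per
#'   frame), `transition` (logical), `onset_frame` (first all-six frame,
#'   1-based, or `NA`), `fraction` (of all-six frames).
#' @export
call_state <- function(probes, thresholds = default_state_thresholds()) {
  need <- c("tm5_rmsd", "helicity", "kink", "water", "sasa_ic", "sasa_t")
  miss <- setdiff(need, names(probes))
  if (length(miss) > 0) {
    stop(mp_error("probe", "missing probe(s): %s", paste(miss, collapse = ", ")))
  }
  len <- vapply(probes[need], function(p) length(p$values), numeric(1))
  if (length(unique(len)) != 1) {
    stop(mp_error("probe", "probe series lengths differ: %s",
                  paste(len, collapse = ", ")))
  }
  thr <- c(tm5_rmsd = thresholds$tm5_rmsd_A, helicity = thresholds$helicity_pct,
           kink = thresholds$kink_deg, water = thresholds$n_water,
           sasa_ic = thresholds$sasa_ic_cavity_A2, sasa_t = thresholds$sasa_t_A2)
  dir <- c(tm5_rmsd = ">=", helicity = "<=", kink = ">=", water = ">=",
           sasa_ic = ">=", sasa_t = ">=")
  flags <- vapply(need, function(n) {
    v <- probes[[n]]$values
    if (dir[n] == ">=") v >= thr[n] else v <= thr[n]
  }, logical(len[1]))
  if (is.null(dim(flags))) flags <- matrix(flags, nrow = 1,
                                           dimnames = list(NULL, need))
  all_six <- rowSums(flags) == length(need)
  onset <- if (any(all_six)) which(all_six)[1] else NA_integer_
  list(flags = flags, all_six = all_six, transition = any(all_six),
       onset_frame = onset, fraction = mean(all_six))
}

#' Assemble the six-probe table of a trajectory
#'
#' One row per frame, one column per probe; column names embed units and
#' thresholds so the table is self-describing.
#'
#' @param probes Named list of [probe_series()].
#' @return data.frame with a `time_ns` column followed by the probes.
#' @export
probe_table <- function(probes) {
  df <- data.frame(time_ns = probes[[1]]$time)
  for (p in probes) {
    nm <- if (is.null(p$threshold)) sprintf("%s_%s", p$name, p$units) else
      sprintf("%s_%s_thr%s%g", p$name, gsub("%", "pct", p$units),
              ifelse(p$direction == ">=", "ge", "le"), p$threshold)
    df[[nm]] <- p$values
  }
  df
}
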