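# Deterministic toy-transporter generator. Builds a poly-alanine helix
# bundle whose residue numbering maps onto the transporter presets, scripts
# an out-to-inward-like transition on its "TM5" helix (unwinding, kinking,
# rigid displacement), populates an intracellular shell with a scripted
# number of waters, and diffuses cholesterol-like beads in a bilayer slab
# with optional planted sticky sites. Every scripted quantity is emitted as
# ground truth, so each probe can be checked against what was planted.

# ideal backbone internal coordinates (Engh-Huber-like values)
.bb <- list(b_NCA = 1.458, b_CAC = 1.525, b_CN = 1.329, b_CO = 1.231,
            b_CACB = 1.521, a_NCAC = 111.2, a_CACN = 116.2, a_CNCA = 121.7,
            a_CACO = 120.5, a_NCACB = 110.4, omega = 180,
            phi_helix = -57, psi_helix = -47,
            phi_ext = -139, psi_ext = 135)

# NeRF: place atom D bonded to C with |CD| = bond, angle(B,C,D) = ang and
# dihedral(A,B,C,D) = tor (degrees)
place_atom <- function(A, B, C, bond, ang, tor) {
  ang <- ang * pi / 180
  tor <- tor * pi / 180
  d2 <- bond * c(-cos(ang), sin(ang) * cos(tor), -sin(ang) * sin(tor))
  bc <- unit(C - B)
  n <- unit(cross3(B - A, bc))
  M <- cbind(bc, cross3(n, bc), n)
  as.vector(M %*% d2 + C)
}

# build a poly-alanine chain (rows per residue: N, CA, C, O, CB) from
# per-residue phi/psi vectors; phi[1] only sets the arbitrary first-residue
# frame
build_peptide <- function(nres, phi, psi) {
  xyz <- matrix(0, nres * 5, 3)
  row <- function(i, name) (i - 1) * 5 + match(name, c("N", "CA", "C", "O",
                                                       "CB"))
  N <- c(0, 0, 0)
  CA <- c(.bb$b_NCA, 0, 0)
  C <- place_atom(c(0, 1, 0), N, CA, .bb$b_CAC, .bb$a_NCAC, phi[1])
  for (i in seq_len(nres)) {
    if (i > 1) {
      Nn <- place_atom(N, CA, C, .bb$b_CN, .bb$a_CACN, psi[i - 1])
      CAn <- place_atom(CA, C, Nn, .bb$b_NCA, .bb$a_CNCA, .bb$omega)
      Cn <- place_atom(C, Nn, CAn, .bb$b_CAC, .bb$a_NCAC, phi[i])
      N <- Nn; CA <- CAn; C <- Cn
    }
    xyz[row(i, "N"), ] <- N
    xyz[row(i, "CA"), ] <- CA
    xyz[row(i, "C"), ] <- C
    xyz[row(i, "O"), ] <- place_atom(N, CA, C, .bb$b_CO, .bb$a_CACO,
                                     psi[i] + 180)
    xyz[row(i, "CB"), ] <- place_atom(C, N, CA, .bb$b_CACB, .bb$a_NCACB,
                                      122.5)
  }
  xyz
}

# helix residue blocks: the full layout tiles the transporter's author
# numbering (58..609) over 12 helices so every preset resolves; the mini
# layout is a reduced bundle for lipid-field fixtures
bundle_blocks <- function(layout = c("full", "mini")) {
  layout <- match.arg(layout)
  if (layout == "full") {
    starts <- c(58, 103, 148, 193, 238, 296, 341, 386, 431, 476, 521, 566)
    ends <- c(102, 147, 192, 237, 295, 340, 385, 430, 475, 520, 565, 609)
  } else {
    starts <- 58 + 12 * (0:11)
    ends <- starts + 11
  }
  Map(c, starts, ends)
}

# helix slot positions: 9-helix outer ring + 3-helix inner core, with the
# TM5 slot on the outer ring flanked by TM1 and TM8 and backed by TM7
bundle_positions <- function(r_outer = 13.2, r_inner = 4.8) {
  ring <- list(H5 = 0, H8 = 40, H3 = 80, H4 = 120, H6 = 160, H9 = 200,
               H10 = 240, H12 = 280, H1 = 320)
  core <- list(H7 = 0, H2 = 120, H11 = 240)
  pos <- matrix(0, 12, 2)
  for (nm in names(ring)) {
    i <- as.integer(sub("H", "", nm))
    a <- ring[[nm]] * pi / 180
    pos[i, ] <- r_outer * c(cos(a), sin(a))
  }
  for (nm in names(core)) {
    i <- as.integer(sub("H", "", nm))
    a <- core[[nm]] * pi / 180
    pos[i, ] <- r_inner * c(cos(a), sin(a))
  }
  pos
}

#' Specification of a synthetic toy-transporter fixture
#'
#' The scripted quantities (`k` unwound residues, kink angle `theta`
#' degrees, rigid TM5 displacement `displacement` Å, Na2-shell water count
#' `n_water`) may each be a scalar or a per-frame vector. When `onset` is a
#' frame index, scalar values apply from that frame on, with a quiescent
#' baseline (0 / 0 / 0 / `n_water_pre`) before it — a step script.
#'
#' @param seed Integer random seed; fully determines the output.
#' @param n_frames Number of frames.
#' @param dt Frame spacing in ns.
#' @param box Orthorhombic box lengths (Å).
#' @param layout `"full"` (presets resolve; 552 residues) or `"mini"`
#'   (reduced bundle for lipid-field fixtures).
#' @param onset Step-script onset frame (1-based) or `NA`.
#' @param k,theta,displacement,n_water Scripted quantities (scalar or
#'   per-frame).
#' @param n_water_pre Baseline water count of a step script.
#' @param n_chol Number of cholesterol-like beads.
#' @param chol_mode `"walk"` (reflected random walk, step `chol_step` Å) or
#'   `"ideal_gas"` (positions independently uniform each frame).
#' @param chol_step Random-walk step standard deviation (Å per frame).
#' @param planted_sites List of sticky sites, each
#'   `list(p = binding probability, radius = jitter radius Å)`; each site
#'   claims one dedicated bead. `NULL` for none.
#' @param noise_sigma Isotropic Gaussian positional noise per protein
#'   coordinate (Å), 0 for noise-free scripts.
#' @param r_outer,r_inner Helix-ring radii (Å).
#' @return Object of class `SyntheticSpec`.
#' @export
synthetic_spec <- function(seed = 1, n_frames = 100, dt = 1,
                           box = c(90, 90, 140),
                           layout = c("full", "mini"), onset = NA,
                           k = 0, theta = 0, displacement = 0, n_water = 3,
                           n_water_pre = 3, n_chol = 40,
                           chol_mode = c("walk", "ideal_gas"),
                           chol_step = 2,
                           planted_sites = list(list(p = 0.5, radius = 2)),
                           noise_sigma = 0, r_outer = 11.4, r_inner = 4.2) {
  layout <- match.arg(layout)
  chol_mode <- match.arg(chol_mode)
  expand <- function(x, base) {
    if (length(x) == n_frames) return(as.numeric(x))
    if (length(x) != 1) {
      stop(mp_error("config", "script length must be 1 or n_frames"))
    }
    if (is.na(onset)) rep(as.numeric(x), n_frames) else
      c(rep(base, onset - 1), rep(as.numeric(x), n_frames - onset + 1))
  }
  sp <- list(seed = as.integer(seed), n_frames = as.integer(n_frames),
             dt = dt, box = box, layout = layout,
             onset = if (is.na(onset)) NA_integer_ else as.integer(onset),
             k = expand(k, 0), theta = expand(theta, 0),
             displacement = expand(displacement, 0),
             n_water = round(expand(n_water, n_water_pre)),
             n_chol = as.integer(n_chol), chol_mode = chol_mode,
             chol_step = chol_step, planted_sites = planted_sites,
             noise_sigma = noise_sigma, r_outer = r_outer,
             r_inner = r_inner)
  if (any(sp$theta < 0 | sp$theta > 180)) {
    stop(mp_error("config", "theta must lie in [0, 180]"))
  }
  if (!is.null(planted_sites)) {
    ps <- vapply(planted_sites, function(s) s$p, numeric(1))
    if (any(ps < 0 | ps > 1)) {
      stop(mp_error("config", "binding probabilities must lie in [0, 1]"))
    }
    if (length(planted_sites) > sp$n_chol) {
      stop(mp_error("config", "more planted sites than beads"))
    }
  }
  blk <- bundle_blocks(layout)
  if (any(sp$k > blk[[5]][2] - blk[[5]][1] + 1)) {
    stop(mp_error("config", "k exceeds the TM5 segment length"))
  }
  structure(sp, class = "SyntheticSpec")
}

# raw-chain dihedral vectors of one helix with `unwound` residue indices
# (1-based within the chain) moved to the extended window
helix_dihedrals <- function(nres, unwound = integer()) {
  phi <- rep(.bb$phi_helix, nres)
  psi <- rep(.bb$psi_helix, nres)
  phi[unwound] <- .bb$phi_ext
  psi[unwound] <- .bb$psi_ext
  list(phi = phi, psi = psi)
}

# rigid placement of a raw helix chain into the bundle: rotation A about
# the raw CA centroid, then translation
apply_placement <- function(raw, pl) {
  sweep(sweep(raw, 2, pl$centroid) %*% t(pl$A), 2, pl$shift, FUN = "+")
}

rotation_to_z <- function(v) {
  v <- unit(v)
  z <- c(0, 0, 1)
  ax <- cross3(v, z)
  s <- sqrt(sum(ax^2))
  if (s < 1e-12) return(diag(3) * sign(sum(v * z)))
  ax <- ax / s
  th <- acos(max(-1, min(1, sum(v * z))))
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Build the toy-transporter helix bundle
#'
#' A 12-helix poly-alanine bundle with full backbone atoms (N, CA, C, O,
#' CB), helices arranged as a 9-membered outer ring around a 3-helix core,
#' with residue numbering mapped onto the transporter presets: the fifth
#' block is "TM5" and carries the hinge residue. Each helix is axially
#' rotated so a designated residue faces the bundle interior, which buries
#' the IC exit-path probes in the resting state. The protein center of mass
#' is placed at the box center.
#'
#' @param spec A [synthetic_spec()].
#' @return List: `top` (protein [topology()] with reference `xyz`),
#'   `layout` (blocks, placements, hinge and derived geometry used by
#'   [script_trajectory()]).
#' @export
build_bundle <- function(spec) {
  blocks <- bundle_blocks(spec$layout)
  pos <- bundle_positions(spec$r_outer, spec$r_inner)
  dpos <- as.matrix(stats::dist(pos))
  diag(dpos) <- Inf
  if (min(dpos) < 7) {
    stop(mp_error("geometry",
      "helices overlap: minimum axis separation %.1f A < 7 A", min(dpos)))
  }
  # residues whose CB is turned toward the bundle interior; for TM5 the
  # exit-path residues 258/262/266/269 share an 80-degree helical arc, so
  # facing 262 inward buries the whole arc in the resting state
  face <- c(`1` = 72, `5` = 262, `6` = 332, `8` = 425, `9` = 432)
  placements <- vector("list", 12)
  coords <- vector("list", 12)
  atoms <- vector("list", 12)
  for (h in 1:12) {
    blk <- blocks[[h]]
    nres <- blk[2] - blk[1] + 1
    dih <- helix_dihedrals(nres)
    raw <- build_peptide(nres, dih$phi, dih$psi)
    ca_rows <- seq(2, nres * 5, 5)
    centroid <- colMeans(raw[ca_rows, , drop = FALSE])
    R1 <- rotation_to_z(principal_axis(raw[ca_rows, , drop = FALSE]))
    # axial spin: face residue CB (or the chain start) points inward
    fr <- face[as.character(h)]
    fres <- if (!is.na(fr) && spec$layout == "full") fr - blk[1] + 1 else 1
    up <- sweep(raw, 2, centroid) %*% t(R1)
    cb <- up[(fres - 1) * 5 + 5, ]
    ca <- up[(fres - 1) * 5 + 2, ]
    v <- cb[1:2] - ca[1:2]
    cur <- atan2(v[2], v[1])
    want <- atan2(-pos[h, 2], -pos[h, 1])
    if (sqrt(sum(pos[h, ]^2)) < 1e-9) want <- cur
    Rz <- matrix(c(cos(want - cur), sin(want - cur), 0,
                   -sin(want - cur), cos(want - cur), 0, 0, 0, 1), 3, 3)
    A <- Rz %*% R1
    pl <- list(A = A, centroid = centroid,
               shift = c(pos[h, 1], pos[h, 2], 0))
    placements[[h]] <- pl
    coords[[h]] <- apply_placement(raw, pl)
    atoms[[h]] <- data.frame(
      name = rep(c("N", "CA", "C", "O", "CB"), nres),
      element = rep(c("N", "C", "C", "O", "C"), nres),
      resno = rep(blk[1]:blk[2], each = 5), resid = "ALA", chain = "A",
      stringsAsFactors = FALSE)
  }
  xyz <- do.call(rbind, coords)
  at <- do.call(rbind, atoms)
  at$eleno <- seq_len(nrow(at))
  # center the protein center of mass at the box center
  m <- atomic_masses()[at$element]
  com <- colSums(xyz * m) / sum(m)
  shift_to_center <- spec$box / 2 - com
  xyz <- sweep(xyz, 2, shift_to_center, FUN = "+")
  for (h in 1:12) {
    placements[[h]]$shift <- placements[[h]]$shift + shift_to_center
  }
  top <- topology(at[, c("eleno", "name", "element", "resno", "resid",
                         "chain")], xyz = xyz)
  tm5 <- blocks[[5]]
  hinge <- if (spec$layout == "full") 273 else tm5[1] + 9
  layout <- list(blocks = blocks, positions = pos, placements = placements,
                 hinge = hinge, tm5_block = tm5,
                 unwind_window = if (spec$layout == "full") 258:273 else
                   (tm5[1] + 2):(tm5[1] + 9),
                 radial = unit(c(pos[5, ], 0)))
  list(top = top, layout = layout)
}

# deterministic water slot positions inside the Na2 shell: three golden
# spiral shells well inside the 10 A cutoff
water_slots <- function(center, n_max = 40) {
  shells <- list(c(2.5, 8), c(4.2, 14), c(5.8, 18))
  pts <- do.call(rbind, lapply(shells, function(s) sphere_points(s[2]) * s[1]))
  sweep(pts[seq_len(n_max), , drop = FALSE], 2, center, FUN = "+")
}

#' Script a synthetic trajectory with ground truth
#'
#' Applies the spec's per-frame scripts to the bundle: `k(t)` TM5 residues
#' rebuilt at extended dihedrals (from the intracellular end of the TM5
#' window), a rigid kink rotation `theta(t)` of the sub-hinge half about a
#' tangential axis through the hinge Cα, a rigid radial displacement
#' `d(t)` of the TM5 IC half, `N(t)` waters placed on fixed slots inside
#' the Na2 shell (surplus waters parked far outside the cutoff),
#' cholesterol-like beads diffusing in the bilayer slab, and planted-site
#' beads bound with per-frame probability `p`. Deterministic for a given
#' seed.
#'
#' @param spec A [synthetic_spec()].
#' @param bundle A [build_bundle()] result (rebuilt when omitted).
#' @return List: `traj` (full-system [trajectory()]), `top` (matching
#'   full [topology()] with frame-1 reference coordinates), `truth`
#'   (per-frame `k`, `theta`, `displacement`, `n_water`, `onset`,
#'   per-site `bound` flags and centers, `seed`, `noise_sigma`).
#' @export
script_trajectory <- function(spec, bundle = build_bundle(spec)) {
  top_p <- bundle$top
  lay <- bundle$layout
  F <- spec$n_frames
  blk5 <- lay$tm5_block
  nres5 <- blk5[2] - blk5[1] + 1
  at_p <- top_p$atoms
  h5_rows <- which(at_p$resno >= blk5[1] & at_p$resno <= blk5[2])
  # rigid displacement moves the whole core-fit-excluded TM5 segment so
  # that no helicity-window dihedral straddles the moving boundary
  disp_seg <- if (spec$layout == "full") c(256, 286) else blk5
  ic_rows <- which(at_p$resno >= disp_seg[1] & at_p$resno <= disp_seg[2])
  sub_hinge_rows <- which(at_p$resno >= blk5[1] &
                            at_p$resno <= lay$hinge - 1)
  kink_seg <- disp_seg
  pre_ca <- which(at_p$resno >= kink_seg[1] &
                    at_p$resno <= lay$hinge - 2 & at_p$name == "CA")
  post_ca <- which(at_p$resno >= lay$hinge + 2 &
                     at_p$resno <= kink_seg[2] & at_p$name == "CA")
  pivot <- top_p$xyz[which(at_p$resno == lay$hinge & at_p$name == "CA"), ]
  tangent <- cross3(c(0, 0, 1), lay$radial)
  rotate_vec <- function(v, axis, ang) {
    as.vector(rotate_about_axis(matrix(v, 1, 3), c(0, 0, 0), axis, ang))
  }
  # Na2 shell center: heavy atoms of the Na2 residues when they exist,
  # otherwise the bundle center at the IC-half height
  na2_res <- c(75, 78, 418, 421, 422)
  na2_rows <- which(at_p$resno %in% na2_res)
  na2_center <- if (spec$layout == "full" && length(na2_rows) > 0) {
    colMeans(top_p$xyz[na2_rows, , drop = FALSE])
  } else {
    c(spec$box[1:2] / 2, mean(top_p$xyz[ic_rows, 3]))
  }
  n_water_max <- max(spec$n_water)
  slots <- if (n_water_max > 0) water_slots(na2_center) else
    matrix(0, 0, 3)
  if (n_water_max > nrow(slots) && n_water_max > 0) {
    stop(mp_error("config",
      "infeasible water script: %d waters exceed the %d-slot shell",
      n_water_max, nrow(slots)))
  }
  park <- cbind(3 + 2.5 * seq_len(max(n_water_max, 1)), 3,
                spec$box[3] - 4)
  # full-system topology: protein + cholesterol beads + waters
  n_chol <- spec$n_chol
  chol_at <- if (n_chol > 0) data.frame(
    name = "C1", element = "C", resno = seq_len(n_chol), resid = "CHL",
    chain = "L", stringsAsFactors = FALSE) else NULL
  wat_at <- if (n_water_max > 0) data.frame(
    name = "O", element = "O", resno = seq_len(n_water_max), resid = "HOH",
    chain = "W", stringsAsFactors = FALSE) else NULL
  at <- rbind(at_p[, c("name", "element", "resno", "resid", "chain")],
              chol_at, wat_at)
  at$eleno <- seq_len(nrow(at))
  natoms <- nrow(at)
  np <- nrow(at_p)
  ci <- if (n_chol > 0) np + seq_len(n_chol) else integer()
  wi <- if (n_water_max > 0) np + n_chol + seq_len(n_water_max) else
    integer()

  set.seed(spec$seed)
  # planted sticky sites near the TM1a/TM5 interface, one dedicated bead
  # each; centers offset outward so unbound bulk excursions never graze them
  sites <- spec$planted_sites
  n_sites <- length(sites)
  site_centers <- NULL
  if (n_sites > 0) {
    base_angle <- atan2(lay$radial[2], lay$radial[1])
    site_centers <- t(vapply(seq_len(n_sites), function(s) {
      a <- base_angle - (20 + 40 * (s - 1)) * pi / 180
      r <- spec$r_outer + 6
      c(spec$box[1] / 2 + r * cos(a), spec$box[2] / 2 + r * sin(a),
        pivot[3] - 12)
    }, numeric(3)))
  }
  slab_z <- spec$box[3] / 2 + c(-12, 12)
  # random-walk lipids are excluded from a cylinder around the bundle (the
  # protein's excluded volume); planted sites sit inside that cylinder, so
  # only deliberately bound beads can satisfy the COM occupancy rule
  r_excl <- spec$r_outer + 12
  bound <- matrix(FALSE, F, n_sites)
  xyz <- matrix(NA_real_, F, 3 * natoms)
  # bulk bead positions (uniform in the slab, outside the exclusion zone)
  draw_bulk <- function(n, avoid = NULL) {
    out <- matrix(0, n, 3)
    for (i in seq_len(n)) {
      repeat {
        p <- c(stats::runif(1, 2, spec$box[1] - 2),
               stats::runif(1, 2, spec$box[2] - 2),
               stats::runif(1, slab_z[1], slab_z[2]))
        far_bundle <- sqrt(sum((p[1:2] - spec$box[1:2] / 2)^2)) > r_excl
        far_sites <- is.null(avoid) ||
          all(sqrt(rowSums(sweep(avoid, 2, p)^2)) > 15)
        if (far_bundle && far_sites) break
      }
      out[i, ] <- p
    }
    out
  }
  chol_pos <- if (n_chol > 0) draw_bulk(n_chol, site_centers) else
    matrix(0, 0, 3)
  base_prot <- top_p$xyz
  prev_active <- NULL
  prot_frame_cache <- NULL
  for (f in seq_len(F)) {
    kf <- spec$k[f]
    th <- spec$theta[f]
    df <- spec$displacement[f]
    active <- c(kf, th, df)
    if (is.null(prev_active) || any(active != prev_active)) {
      co <- base_prot
      if (kf > 0) {
        win <- lay$unwind_window
        unw <- (max(win) - kf + 1):max(win) - blk5[1] + 1
        dih <- helix_dihedrals(nres5, unw)
        raw <- build_peptide(nres5, dih$phi, dih$psi)
        co[h5_rows, ] <- apply_placement(raw, lay$placements[[5]])
      }
      if (th != 0) {
        # realise the scripted axis angle exactly: tilt the sub-hinge half
        # so its principal axis lands at theta degrees from the post-hinge
        # axis, opening toward the bundle exterior
        a1 <- principal_axis(co[pre_ca, , drop = FALSE])
        a2 <- principal_axis(co[post_ca, , drop = FALSE])
        a1_target <- rotate_vec(a2, tangent, -th)
        w <- cross3(a1, a1_target)
        ang <- acos(max(-1, min(1, sum(a1 * a1_target)))) * 180 / pi
        if (sqrt(sum(w^2)) > 1e-12 && ang > 1e-9) {
          co[sub_hinge_rows, ] <- rotate_about_axis(
            co[sub_hinge_rows, , drop = FALSE], pivot, w, ang)
        }
      }
      if (df != 0) {
        co[ic_rows, ] <- sweep(co[ic_rows, , drop = FALSE], 2,
                               df * lay$radial, FUN = "+")
      }
      prot_frame_cache <- co
      prev_active <- active
    }
    co <- prot_frame_cache
    if (spec$noise_sigma > 0) {
      co <- co + matrix(stats::rnorm(length(co), 0, spec$noise_sigma),
                        nrow(co), 3)
    }
    frame <- matrix(NA_real_, natoms, 3)
    frame[seq_len(np), ] <- co
    if (n_chol > 0) {
      if (spec$chol_mode == "ideal_gas") {
        chol_pos <- cbind(stats::runif(n_chol, 0, spec$box[1]),
                          stats::runif(n_chol, 0, spec$box[2]),
                          stats::runif(n_chol, slab_z[1], slab_z[2]))
      } else {
        step <- matrix(stats::rnorm(3 * n_chol, 0, spec$chol_step),
                       n_chol, 3)
        step[, 3] <- step[, 3] * 0.3  # lipids stay near their leaflet
        chol_pos <- chol_pos + step
        for (kdim in 1:2) {
          chol_pos[, kdim] <- abs(chol_pos[, kdim])
          over <- chol_pos[, kdim] > spec$box[kdim]
          chol_pos[over, kdim] <- 2 * spec$box[kdim] - chol_pos[over, kdim]
        }
        chol_pos[, 3] <- pmin(pmax(chol_pos[, 3], slab_z[1]), slab_z[2])
        # reflect walkers off the protein-exclusion cylinder
        rel <- sweep(chol_pos[, 1:2, drop = FALSE], 2, spec$box[1:2] / 2)
        rr <- sqrt(rowSums(rel^2))
        inside <- rr < r_excl
        if (any(inside)) {
          scale <- (2 * r_excl - rr[inside]) / pmax(rr[inside], 1e-9)
          rel[inside, ] <- rel[inside, , drop = FALSE] * scale
          chol_pos[inside, 1:2] <- sweep(rel[inside, , drop = FALSE], 2,
                                         spec$box[1:2] / 2, FUN = "+")
        }
      }
      if (n_sites > 0) {
        for (s in seq_len(n_sites)) {
          bnd <- stats::runif(1) < sites[[s]]$p
          bound[f, s] <- bnd
          if (bnd) {
            jit <- stats::runif(3, -1, 1)
            jit <- jit / max(1, sqrt(sum(jit^2))) * sites[[s]]$radius *
              stats::runif(1)^(1 / 3)
            chol_pos[s, ] <- site_centers[s, ] + jit
          } else {
            chol_pos[s, ] <- draw_bulk(1, site_centers)
          }
        }
      }
      frame[ci, ] <- chol_pos
    }
    if (n_water_max > 0) {
      nw <- spec$n_water[f]
      wpos <- park[seq_len(n_water_max), , drop = FALSE]
      if (nw > 0) wpos[seq_len(nw), ] <- slots[seq_len(nw), , drop = FALSE]
      frame[wi, ] <- wpos
    }
    xyz[f, ] <- as.vector(t(frame))
  }
  top <- topology(at[, c("eleno", "name", "element", "resno", "resid",
                         "chain")],
                  xyz = matrix(xyz[1, ], ncol = 3, byrow = TRUE))
  traj <- trajectory(xyz, spec$box, time = spec$dt * (seq_len(F) - 1))
  truth <- list(k = spec$k, theta = spec$theta,
                displacement = spec$displacement, n_water = spec$n_water,
                onset = spec$onset, bound = bound,
                site_centers = site_centers, seed = spec$seed,
                noise_sigma = spec$noise_sigma)
  list(traj = traj, top = top, truth = truth)
}

#' Write a synthetic fixture to disk
#'
#' Emits the multi-model PDB trajectory, a single-model topology PDB, the
#' ground-truth JSON and the generating spec YAML. Byte-identical for
#' identical specs (same seed included).
#'
#' @param fix A [script_trajectory()] result.
#' @param spec The generating [synthetic_spec()].
#' @param dir Output directory (created if missing).
#' @return Named character vector of the paths written.
#' @export
write_fixture <- function(fix, spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(trajectory = file.path(dir, "trajectory.pdb"),
             topology = file.path(dir, "topology.pdb"),
             truth = file.path(dir, "truth.json"),
             spec = file.path(dir, "spec.yaml"))
  write_trajectory_pdb(fix$traj, fix$top, paths["trajectory"])
  ref <- trajectory(matrix(fix$traj$xyz[1, ], nrow = 1),
                    fix$traj$box[1, ])
  write_trajectory_pdb(ref, fix$top, paths["topology"])
  tr <- fix$truth
  tr$bound <- if (is.null(tr$bound)) NULL else unname(as.matrix(tr$bound))
  jsonlite::write_json(tr, paths["truth"], digits = NA, auto_unbox = TRUE,
                       na = "null", matrix = "rowmajor")
  yaml::write_yaml(unclass(spec), paths["spec"])
  invisible(paths)
}
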