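# The six-probe suite, RMSF, gates and the state caller.

test_that("tm5_rmsd is zero for the reference and recovers displacement", {
  nul <- fx_null()
  pr <- hdat_presets()
  expect_lt(max(tm5_rmsd(nul$traj, nul$top, pr)$values), 1e-8)
  # scripted rigid displacement of the TM5 IC half
  d <- 3
  sp <- synthetic_spec(seed = 40, n_frames = 2, onset = 2, displacement = d,
                       n_chol = 0, planted_sites = NULL)
  fix <- script_trajectory(sp)
  r <- tm5_rmsd(fix$traj, fix$top, pr)$values
  expect_equal(r[1], 0, tolerance = 1e-8)
  expect_equal(r[2], d, tolerance = 0.01)
  # a globally rotated frame is removable rigid motion
  rot <- cbind(c(0, 1, 0), c(-1, 0, 0), c(0, 0, 1))
  moved <- nul$top$xyz %*% rot
  tr <- trajectory(matrix(as.vector(t(moved)), 1), nul$traj$box[1, ])
  expect_lt(tm5_rmsd(tr, nul$top, pr)$values, 1e-6)
})

test_that("RMSF matches closed forms", {
  top <- scatter_topology(20, seed = 9)
  expect_error(per_residue_rmsf(static_trajectory(top, 1), top, 1:20),
               "2 frames")
  # static: all zero
  r0 <- per_residue_rmsf(static_trajectory(top, 4), top, 1:20)
  expect_lt(max(r0$rmsf), 1e-8)
  # one atom oscillating A*sin over whole periods -> RMSF = A/sqrt(2)
  A <- 2
  nf <- 40
  frames <- matrix(rep(as.vector(t(top$xyz)), each = nf), nrow = nf)
  osc <- A * sin(2 * pi * (0:(nf - 1)) / 8)
  frames[, 3 * 20] <- frames[, 3 * 20] + osc  # z of atom 20
  tr <- trajectory(frames, c(100, 100, 100))
  r <- per_residue_rmsf(tr, top, 1:19, reference = top$xyz)
  expect_equal(r$rmsf[20], A / sqrt(2), tolerance = 0.02 * A)
  expect_lt(max(r$rmsf[1:19]), 1e-8)
})

test_that("RMSF of isotropic per-residue noise approaches sigma*sqrt(3)", {
  sig <- 0.3
  sp <- synthetic_spec(seed = 41, n_frames = 60, layout = "mini",
                       n_chol = 0, planted_sites = NULL, noise_sigma = sig)
  fix <- script_trajectory(sp)
  r <- per_residue_rmsf(fix$traj, fix$top, all_ca_selection(fix$top))
  expect_equal(mean(r$rmsf), sig * sqrt(3), tolerance = 0.05 * sig * sqrt(3))
})

test_that("helicity follows the dihedral window", {
  # ideal alpha helix: 100% (terminal residues leave the denominator)
  hel16 <- memprobe:::build_peptide(16, rep(-57, 16), rep(-47, 16))
  at <- data.frame(name = rep(c("N", "CA", "C", "O", "CB"), 16),
                   element = rep(c("N", "C", "C", "O", "C"), 16),
                   resno = rep(1:16, each = 5), resid = "ALA", chain = "A")
  top <- make_topology(at, hel16)
  tr <- static_trajectory(top)
  expect_equal(helicity(tr, top, 1:16)$values, 100)
  # fully extended chain: 0%
  ext <- memprobe:::build_peptide(16, rep(-139, 16), rep(135, 16))
  texts <- make_topology(at, ext)
  expect_equal(helicity(static_trajectory(texts), texts, 1:16)$values, 0)
  # scripted k non-helical residues: exact to one residue quantum
  pr <- hdat_presets()
  for (k in c(3, 8, 12)) {
    sp <- synthetic_spec(seed = 42, n_frames = 2, onset = 2, k = k,
                         n_chol = 0, planted_sites = NULL)
    fix <- script_trajectory(sp)
    h <- helicity(fix$traj, fix$top, pr$tm5_ic_half)$values
    expect_equal(h, c(100, 100 * (16 - k) / 16))
  }
  # missing backbone atoms are reported by residue
  broken <- make_topology(at[at$resno != 7 | at$name != "N", ],
                          hel16[!(at$resno == 7 & at$name == "N"), ])
  expect_error(helicity(static_trajectory(broken), broken, 1:16), "7")
})

test_that("kink angle recovers constructed rotations without wrapping", {
  # straight ideal helix with five full turns per sub-segment
  n <- 43
  hel <- memprobe:::build_peptide(n, rep(-57, n), rep(-47, n))
  at <- data.frame(name = rep(c("N", "CA", "C", "O", "CB"), n),
                   element = rep(c("N", "C", "C", "O", "C"), n),
                   resno = rep(1:n, each = 5), resid = "ALA", chain = "A")
  top <- make_topology(at, hel)
  hinge <- 22
  tr <- static_trajectory(top)
  k0 <- kink_angle(tr, top, 1:n, hinge)
  expect_lt(k0$series$values, 2)  # axis wobble only
  expect_equal(sqrt(rowSums(k0$axis_pre^2)), 1, tolerance = 1e-9)
  # rotate the post-hinge half by exactly 30 (then 150) degrees about an
  # axis through the hinge CA perpendicular to the helix axis
  ca_rows <- seq(2, n * 5, 5)
  post_atoms <- which(at$resno >= hinge + 1)
  pivot <- hel[ca_rows[hinge], ]
  a1 <- memprobe:::principal_axis(hel[ca_rows[1:(hinge - 2)], ])
  perp <- memprobe:::unit(memprobe:::cross3(a1, c(1, 0, 0)))
  for (theta in c(30, 150)) {
    rot <- hel
    rot[post_atoms, ] <- memprobe:::rotate_about_axis(hel[post_atoms, ],
                                                      pivot, perp, theta)
    trr <- trajectory(matrix(as.vector(t(rot)), 1), c(100, 100, 100))
    kr <- kink_angle(trr, top, 1:n, hinge)$series$values
    expect_equal(kr, theta, tolerance = 1)
  }
})

test_that("scripted kink angles are recovered on the toy bundle", {
  pr <- hdat_presets()
  for (theta in c(25, 150)) {
    sp <- synthetic_spec(seed = 43, n_frames = 2, onset = 2, theta = theta,
                         n_chol = 0, planted_sites = NULL)
    fix <- script_trajectory(sp)
    k <- kink_angle(fix$traj, fix$top, pr$tm5_full, pr$tm5_hinge)
    expect_equal(k$series$values[2], theta, tolerance = 1)
    expect_true(all(k$series$values >= 0 & k$series$values <= 180))
  }
})

test_that("water count applies the cutoff to planted distances", {
  # site of one CA at origin; three waters at 4, 9.9, 10.1 A
  at <- data.frame(name = c("CA", "O", "O", "O"),
                   element = c("C", "O", "O", "O"),
                   resno = c(1, 2, 3, 4),
                   resid = c("ALA", "HOH", "HOH", "HOH"), chain = "A")
  xyz <- rbind(c(0, 0, 0), c(4, 0, 0), c(9.9, 0, 0), c(10.1, 0, 0))
  top <- make_topology(at, xyz)
  tr <- static_trajectory(top)
  expect_equal(water_count(tr, top, selection(1))$values, 2)
  # no waters at all: zero for all frames
  top2 <- make_topology(at[1, , drop = FALSE], xyz[1, , drop = FALSE])
  expect_equal(water_count(static_trajectory(top2, 3), top2,
                           selection(1))$values, c(0, 0, 0))
  # scripted shell filling is recovered exactly
  nw <- c(0, 3, 9, 15, 20, 20)
  sp <- synthetic_spec(seed = 44, n_frames = 6, n_water = nw, n_chol = 0,
                       planted_sites = NULL)
  fix <- script_trajectory(sp)
  wc <- water_count(fix$traj, fix$top,
                    selection(hdat_presets()$na2_site))
  expect_equal(wc$values, nw)
})

test_that("gate distances implement the three contact classes", {
  # Arg/Asp salt bridge with nearest N-O planted at 2.8 A
  at <- data.frame(
    name = c("NE", "NH1", "NH2", "OD1", "OD2"),
    element = c("N", "N", "N", "O", "O"),
    resno = c(1, 1, 1, 2, 2),
    resid = c("ARG", "ARG", "ARG", "ASP", "ASP"), chain = "A")
  xyz <- rbind(c(0, 0, 0), c(-1, 1, 0), c(-1, -1, 0),
               c(2.8, 0, 0), c(5, 1, 0))
  top <- make_topology(at, xyz)
  pairs <- data.frame(label = "R1-D2", a = 1, b = 2, type = "salt_bridge")
  g <- gate_distances(static_trajectory(top), top, pairs)
  expect_equal(g[[1]]$distances, 2.8)
  # two Phe rings with centroids 5 A apart
  ring <- c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")
  hexagon <- t(vapply(0:5, function(i) {
    1.39 * c(cos(i * pi / 3), sin(i * pi / 3), 0)
  }, numeric(3)))
  at2 <- data.frame(name = rep(ring, 2), element = "C",
                    resno = rep(1:2, each = 6), resid = "PHE", chain = "A")
  xyz2 <- rbind(hexagon, sweep(hexagon, 2, c(0, 0, 5), FUN = "+"))
  top2 <- make_topology(at2, xyz2)
  g2 <- gate_distances(static_trajectory(top2), top2,
                       data.frame(label = "F1-F2", a = 1, b = 2,
                                  type = "aromatic"))
  expect_equal(g2[[1]]$distances, 5)
  # polar pair: Ser hydroxyl to Asp carboxylate, order-agnostic
  at3 <- data.frame(name = c("OG", "OD1", "OD2"), element = "O",
                    resno = c(10, 20, 20), resid = c("SER", "ASP", "ASP"),
                    chain = "A")
  xyz3 <- rbind(c(0, 0, 0), c(3.1, 0, 0), c(6, 0, 0))
  top3 <- make_topology(at3, xyz3)
  g3 <- gate_distances(static_trajectory(top3), top3,
                       data.frame(label = "D20-S10", a = 20, b = 10,
                                  type = "polar"))
  expect_equal(g3[[1]]$distances, 3.1)
  # incompatible residue type
  expect_error(gate_distances(static_trajectory(top3), top3,
                              data.frame(label = "bad", a = 10, b = 10,
                                         type = "aromatic")),
               "incompatible")
})

test_that("salt-bridge distance equals the exhaustive pairwise minimum", {
  at <- data.frame(name = c("NE", "NH1", "NH2", "OE1", "OE2"),
                   element = c("N", "N", "N", "O", "O"),
                   resno = c(1, 1, 1, 2, 2),
                   resid = c("ARG", "ARG", "ARG", "GLU", "GLU"),
                   chain = "A")
  for (seed in 1:5) {
    set.seed(seed)
    xyz <- matrix(stats::runif(15, -5, 5), 5, 3)
    top <- make_topology(at, xyz)
    g <- gate_distances(static_trajectory(top), top,
                        data.frame(label = "p", a = 1, b = 2,
                                   type = "salt_bridge"))
    brute <- min(as.matrix(stats::dist(xyz))[1:3, 4:5])
    expect_equal(g[[1]]$distances, brute)
  }
})

test_that("probe values are invariant under a global rigid transform", {
  sp <- synthetic_spec(seed = 45, n_frames = 2, onset = 2, k = 4,
                       theta = 25, displacement = 4, n_water = 10,
                       n_chol = 0, planted_sites = NULL)
  fix <- script_trajectory(sp)
  pr <- hdat_presets()
  rot <- qr.Q(qr(matrix(c(1, 2, 3, 4, 5, 6, 7, 8, 10), 3)))
  if (det(rot) < 0) rot[, 1] <- -rot[, 1]
  shift <- c(4, -3, 7)
  moved <- t(vapply(seq_len(fix$traj$nframes), function(f) {
    as.vector(t(sweep(traj_frame(fix$traj, f) %*% rot, 2, shift,
                      FUN = "+")))
  }, numeric(ncol(fix$traj$xyz))))
  trm <- trajectory(moved, fix$traj$box, fix$traj$time)
  topm <- fix$top
  topm$xyz <- sweep(topm$xyz %*% rot, 2, shift, FUN = "+")
  for (getter in list(
    function(tr, tp) tm5_rmsd(tr, tp, pr)$values,
    function(tr, tp) helicity(tr, tp, pr$tm5_ic_half)$values,
    function(tr, tp) kink_angle(tr, tp, pr$tm5_full, pr$tm5_hinge)$series$values,
    function(tr, tp) water_count(tr, tp, selection(pr$na2_site))$values)) {
    expect_equal(getter(trm, topm), getter(fix$traj, fix$top),
                 tolerance = 1e-6)
  }
  # SASA is invariant up to the point-sampling resolution of the sphere grid
  s_ref <- sasa(traj_frame(fix$traj, 2), fix$top,
                selection(pr$ic_exit_path), n_points = 960)$total
  s_mov <- sasa(traj_frame(trm, 2), topm,
                selection(pr$ic_exit_path), n_points = 960)$total
  expect_equal(s_mov, s_ref, tolerance = 0.02)
})

test_that("state caller is inclusive at thresholds and monotone", {
  thr <- default_state_thresholds()
  mk <- function(name, v, units, t, dir) probe_series(name, v, units, t, dir)
  at_thr <- list(
    tm5_rmsd = mk("tm5_rmsd", c(5, 0), "A", 5, ">="),
    helicity = mk("helicity", c(50, 100), "%", 50, "<="),
    kink = mk("kink", c(20, 0), "deg", 20, ">="),
    water = mk("water", c(15, 0), "count", 15, ">="),
    sasa_ic = mk("sasa_ic", c(220, 0), "A2", 220, ">="),
    sasa_t = mk("sasa_t", c(50, 0), "A2", 50, ">="))
  st <- call_state(at_thr, thr)
  expect_true(all(st$flags[1, ]))  # boundary values count, inclusively
  expect_false(any(st$flags[2, ]))
  expect_true(st$transition)
  expect_equal(st$onset_frame, 1)
  # raising a ">=" threshold never increases the transition-frame count
  thr2 <- thr
  thr2$kink_deg <- 21
  expect_lte(sum(call_state(at_thr, thr2)$all_six), sum(st$all_six))
  # length mismatch
  bad <- at_thr
  bad$water <- mk("water", c(15, 0, 1), "count", 15, ">=")
  expect_error(call_state(bad), "lengths differ")
})

test_that("state caller finds the scripted onset and rejects the null", {
  stp <- fx_step()
  st <- call_state(six_probes(stp))
  expect_true(st$transition)
  expect_lte(abs(st$onset_frame - stp$spec$onset), 5)
  nul <- fx_null()
  expect_false(call_state(six_probes(nul))$transition)
})
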