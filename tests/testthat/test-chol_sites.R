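# Occupancy grids, site detection, COM occupancy rules, event counting.

# protein cluster at the box center plus controllable cholesterol beads
chol_system <- function(bead_frames, box = c(60, 60, 60)) {
  n_beads <- ncol(bead_frames) / 3
  prot <- scatter_topology(12, seed = 12, radius = 2.5)
  at <- rbind(
    data.frame(name = "CA", element = "C", resno = 1:12, resid = "ALA",
               chain = "A"),
    data.frame(name = "C1", element = "C", resno = seq_len(n_beads),
               resid = "CHL", chain = "L"))
  prot_xyz <- sweep(prot$xyz, 2, box / 2, FUN = "+")
  top <- make_topology(at, rbind(prot_xyz,
                                 matrix(bead_frames[1, ], n_beads, 3,
                                        byrow = TRUE)))
  nf <- nrow(bead_frames)
  xyz <- cbind(matrix(rep(as.vector(t(prot_xyz)), each = nf), nrow = nf),
               bead_frames)
  list(top = top, traj = trajectory(xyz, box))
}

test_that("occupancy counts occupied-frame fractions exactly", {
  # bead A stationary near the protein; bead B sweeps the bulk shell
  nf <- 100
  posA <- matrix(rep(c(36.2, 30.2, 30.2), each = nf), nrow = nf)
  # B: in one voxel for 37 frames, elsewhere after
  posB <- matrix(rep(c(10.2, 10.2, 30.2), each = nf), nrow = nf)
  posB[38:nf, 1] <- 50.2
  sys <- chol_system(cbind(posA, posB))
  grid <- build_occupancy_grid(sys$traj, sys$top, 1:12, voxel = 2,
                               bulk_shell = c(5, 25),
                               membrane_halfwidth = 30)
  occ_at <- function(p) {
    i <- floor((p - grid$origin) / grid$voxel) + 1
    grid$occupancy[i[1], i[2], i[3]]
  }
  expect_equal(occ_at(c(36.2, 30.2, 30.2)), 1.0)
  expect_equal(occ_at(c(10.2, 10.2, 30.2)), 0.37)
  # histogram property: frame order is irrelevant
  perm <- sample(nf)
  sys2 <- chol_system(cbind(posA[perm, ], posB[perm, ]))
  grid2 <- build_occupancy_grid(sys2$traj, sys2$top, 1:12, voxel = 2,
                                bulk_shell = c(5, 25),
                                membrane_halfwidth = 30)
  expect_equal(grid2$occupancy, grid$occupancy)
  # no lipids is an error
  prot_only <- scatter_topology(5, seed = 13)
  expect_error(build_occupancy_grid(static_trajectory(prot_only), prot_only,
                                    1:5, voxel = 2), "class")
})

test_that("site detection separates connected components", {
  mk_grid <- function(occ, bulk) {
    structure(list(origin = c(0, 0, 0), voxel = 1, dim = dim(occ),
                   occupancy = occ, bulk = bulk, nframes = 100,
                   reference = matrix(c(2, 2, 2), 1, 3)),
              class = "OccupancyGrid")
  }
  top1 <- make_topology(data.frame(name = "CA", element = "C", resno = 1,
                                   resid = "ALA", chain = "A"),
                        matrix(c(2, 2, 2), 1, 3))
  # one super-threshold voxel
  occ <- array(0.01, c(5, 5, 5))
  occ[3, 3, 3] <- 0.5
  s1 <- detect_sites(mk_grid(occ, 0.01), top1, matrix(c(2, 2, 2), 1, 3))
  expect_length(s1, 1)
  expect_equal(s1[[1]]$centroid, c(2.5, 2.5, 2.5))
  expect_equal(s1[[1]]$resno, 1)  # within 6 A of the voxel center
  # two blobs separated by sub-threshold voxels -> exactly two sites
  occ2 <- array(0.01, c(7, 5, 5))
  occ2[1:2, 3, 3] <- 0.4
  occ2[6:7, 3, 3] <- 0.6
  s2 <- detect_sites(mk_grid(occ2, 0.01), top1, matrix(c(2, 2, 2), 1, 3))
  expect_length(s2, 2)
  expect_equal(s2[[1]]$peak_enrichment, 60)  # sorted by peak enrichment
  # every member voxel satisfies the enrichment invariant
  for (s in s2) {
    idx <- floor(sweep(s$voxels, 2, c(0, 0, 0)))
    vals <- apply(idx + 1, 1, function(i) occ2[i[1], i[2], i[3]])
    expect_true(all(vals >= 3 * 0.01))
  }
  # zero bulk refuses to call sites
  expect_error(detect_sites(mk_grid(occ, 0), top1, matrix(c(2, 2, 2), 1, 3)),
               "bulk")
})

test_that("site occupancy fraction implements the strict any-molecule rule", {
  nf <- 100
  # one bead within 8 A of the site residue COM for exactly half the frames
  near <- c(34, 30, 30)  # ~4 A from the cluster center
  far <- c(55, 55, 55)
  pos <- matrix(rep(far, each = nf), nrow = nf)
  pos[1:50, ] <- matrix(rep(near, each = nf / 2), nrow = nf / 2)
  sys <- chol_system(pos)
  expect_equal(site_occupancy_fraction(sys$traj, sys$top, 1:12, cutoff = 8),
               0.5)
  # never within 20 A
  pos0 <- matrix(rep(far, each = nf), nrow = nf)
  sys0 <- chol_system(pos0)
  expect_equal(site_occupancy_fraction(sys0$traj, sys0$top, 1:12), 0)
  # two beads with disjoint bound frames covering 80%
  posA <- matrix(rep(far, each = nf), nrow = nf)
  posA[1:40, ] <- matrix(rep(near, each = 40), nrow = 40)
  posB <- matrix(rep(far + 5, each = nf), nrow = nf)
  posB[41:80, ] <- matrix(rep(near + 0.5, each = 40), nrow = 40)
  sys2 <- chol_system(cbind(posA, posB))
  expect_equal(site_occupancy_fraction(sys2$traj, sys2$top, 1:12), 0.8)
  # monotone non-decreasing in the cutoff
  fr <- vapply(c(4, 6, 8, 12), function(cut) {
    site_occupancy_fraction(sys2$traj, sys2$top, 1:12, cutoff = cut)
  }, numeric(1))
  expect_true(all(diff(fr) >= 0))
})

test_that("bound traces use a strict cutoff and count events by runs", {
  nf <- 3
  com <- c(30, 30, 30)  # COM of the 12-atom cluster is near the box center
  sysd <- chol_system(matrix(0, nf, 3))
  site_com <- memprobe:::com_series(sysd$traj, sysd$top, 1:12)[1, ]
  pos <- rbind(site_com + c(4.9, 0, 0), site_com + c(5.0, 0, 0),
               site_com + c(5.1, 0, 0))
  sys <- chol_system(pos)
  bt <- bound_trace(sys$traj, sys$top, 1, 1:12, cutoff = 5, chain = "L")
  expect_equal(bt$distances, c(4.9, 5.0, 5.1), tolerance = 1e-9)
  expect_equal(bt$bound, c(TRUE, FALSE, FALSE))  # strictly below 5
  # molecule pinned at the site COM
  sysp <- chol_system(matrix(rep(site_com, each = 4), nrow = 4))
  btp <- bound_trace(sysp$traj, sysp$top, 1, 1:12, chain = "L")
  expect_true(all(btp$bound))
  expect_lt(max(btp$distances), 1e-9)
  # wrong molecule class
  expect_error(bound_trace(sys$traj, sys$top, 1, 1:12, chain = "A"),
               "class")
  # event counting against run-length enumeration
  mk_trace <- function(b) structure(list(bound = b, time = seq_along(b) - 1),
                                    class = "BoundTrace")
  ev <- count_binding_events(mk_trace(rep(TRUE, 5)))
  expect_equal(ev$n_binding, 0)
  expect_equal(ev$n_unbinding, 0)
  expect_equal(ev$dwell_times, 5)
  ev2 <- count_binding_events(mk_trace(c(FALSE, TRUE, FALSE, TRUE)))
  expect_equal(ev2$n_binding, 2)
  expect_equal(ev2$n_unbinding, 1)
  expect_equal(ev2$dwell_times, c(1, 1))
  ev0 <- count_binding_events(mk_trace(rep(FALSE, 4)))
  expect_equal(ev0$n_binding, 0)
  expect_length(ev0$dwell_times, 0)
  set.seed(14)
  for (i in 1:5) {
    b <- stats::runif(50) < 0.5
    ev <- count_binding_events(mk_trace(b))
    expect_equal(ev$n_binding, sum(diff(b) == 1))
    expect_equal(ev$n_unbinding, sum(diff(b) == -1))
    r <- rle(b)
    expect_equal(ev$dwell_times, r$lengths[r$values])
  }
})

test_that("planted-site fixtures are recovered from the grid and COM rules", {
  walk <- fx_chol_walk()
  wgrid <- build_occupancy_grid(walk$traj, walk$top,
                                all_ca_selection(walk$top), voxel = 2)
  wsites <- detect_sites(wgrid, walk$top)
  frac <- site_occupancy_fraction(walk$traj, walk$top, wsites[[1]])
  # the measured fraction equals the planted bound fraction exactly and the
  # planted probability within binomial error (3 sigma at 2000 frames)
  expect_equal(frac, mean(walk$truth$bound[, 1]))
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 2000))
  gas <- fx_chol_gas_planted()
  grid <- build_occupancy_grid(gas$traj, gas$top,
                               all_ca_selection(gas$top), voxel = 2)
  sites <- detect_sites(grid, gas$top)
  expect_length(sites, 1)
  err <- sqrt(sum((sites[[1]]$centroid - gas$truth$site_centers[1, ])^2))
  expect_lt(err, 2 * grid$voxel)
  expect_gte(sites[[1]]$peak_enrichment, 3)
})

test_that("the ideal-gas control yields no enriched sites", {
  ctl <- fx_chol_gas_control()
  grid <- build_occupancy_grid(ctl$traj, ctl$top,
                               all_ca_selection(ctl$top), voxel = 2)
  expect_gt(grid$bulk, 0)
  expect_length(detect_sites(grid, ctl$top), 0)
})

test_that("site detection is invariant under a consistent rigid transform", {
  gas <- fx_chol_gas_planted()
  grid <- build_occupancy_grid(gas$traj, gas$top,
                               all_ca_selection(gas$top), voxel = 2)
  sites <- detect_sites(grid, gas$top)
  # lattice-preserving transform (quarter turn, voxel-multiple shift), so
  # the voxelisation is congruent and the comparison is exact
  rot <- cbind(c(0, 1, 0), c(-1, 0, 0), c(0, 0, 1))
  shift <- c(8, -2, 4)
  move <- function(m) sweep(m %*% rot, 2, shift, FUN = "+")
  topm <- gas$top
  topm$xyz <- move(gas$top$xyz)
  xyzm <- t(vapply(seq_len(gas$traj$nframes), function(f) {
    as.vector(t(move(traj_frame(gas$traj, f))))
  }, numeric(ncol(gas$traj$xyz))))
  trm <- trajectory(xyzm, gas$traj$box)
  gridm <- build_occupancy_grid(trm, topm, all_ca_selection(topm),
                                reference = topm$xyz, voxel = 2)
  sitesm <- detect_sites(gridm, topm)
  expect_length(sitesm, length(sites))
  expect_equal(sort(sitesm[[1]]$resno), sort(sites[[1]]$resno))
  expect_equal(sitesm[[1]]$peak_enrichment, sites[[1]]$peak_enrichment,
               tolerance = 1e-9)
})

test_that("occupancy grids serialise to OpenDX", {
  gas <- fx_chol_gas_planted()
  grid <- build_occupancy_grid(gas$traj, gas$top,
                               all_ca_selection(gas$top), voxel = 2)
  f <- withr::local_tempfile(fileext = ".dx")
  write_dx(grid, f)
  lines <- readLines(f)
  expect_match(lines[1], sprintf("counts %d %d %d", grid$dim[1],
                                 grid$dim[2], grid$dim[3]))
  nums <- as.numeric(unlist(strsplit(paste(
    lines[8:(7 + ceiling(prod(grid$dim) / 3))], collapse = " "), " +")))
  nums <- nums[!is.na(nums)]
  expect_length(nums, prod(grid$dim))
  expect_equal(max(nums), max(grid$occupancy), tolerance = 1e-5)
})
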