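# Shared fixtures, built once per test run and cached.

.fx_cache <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (!exists(name, envir = .fx_cache)) {
    assign(name, builder(), envir = .fx_cache)
  }
  get(name, envir = .fx_cache)
}

hdat_presets <- function() {
  fx("presets", function() load_selection_presets("hdat"))
}

# quiescent full bundle, no lipids/waters beyond baseline
fx_null <- function() {
  fx("null", function() {
    sp <- synthetic_spec(seed = 101, n_frames = 6, n_chol = 0,
                         planted_sites = NULL)
    c(script_trajectory(sp), list(spec = sp))
  })
}

# step-transition fixture: all six probes cross their thresholds at onset
fx_step <- function() {
  fx("step", function() {
    sp <- synthetic_spec(seed = 102, n_frames = 30, onset = 16, k = 8,
                         theta = 30, displacement = 8, n_water = 20,
                         n_chol = 0, planted_sites = NULL)
    c(script_trajectory(sp), list(spec = sp))
  })
}

# six-probe list for a generated fixture
six_probes <- function(fixture, n_points = 480) {
  pr <- hdat_presets()
  traj <- fixture$traj
  top <- fixture$top
  list(
    tm5_rmsd = tm5_rmsd(traj, top, pr),
    helicity = helicity(traj, top, pr$tm5_ic_half),
    kink = kink_angle(traj, top, pr$tm5_full, pr$tm5_hinge)$series,
    water = water_count(traj, top, selection(pr$na2_site)),
    sasa_ic = sasa_series(traj, top, selection(pr$ic_exit_path),
                          name = "sasa_ic", n_points = n_points),
    sasa_t = sasa_series(traj, top, selection(pr$t_probe),
                         name = "sasa_t", n_points = n_points))
}

# cholesterol fixtures on the mini bundle; 2000 frames so that a 3x-bulk
# voxel excursion is excluded at the binomial tail bound
fx_chol_walk <- function() {
  fx("chol_walk", function() {
    sp <- synthetic_spec(seed = 103, n_frames = 2000, layout = "mini",
                         n_chol = 200, chol_mode = "walk", n_water = 0,
                         planted_sites = list(list(p = 0.5, radius = 2)))
    c(script_trajectory(sp), list(spec = sp))
  })
}

fx_chol_gas_planted <- function() {
  fx("chol_gas_planted", function() {
    sp <- synthetic_spec(seed = 104, n_frames = 2000, layout = "mini",
                         n_chol = 200, chol_mode = "ideal_gas", n_water = 0,
                         planted_sites = list(list(p = 0.5, radius = 2)))
    c(script_trajectory(sp), list(spec = sp))
  })
}

fx_chol_gas_control <- function() {
  fx("chol_gas_control", function() {
    sp <- synthetic_spec(seed = 105, n_frames = 2000, layout = "mini",
                         n_chol = 200, chol_mode = "ideal_gas", n_water = 0,
                         planted_sites = NULL)
    c(script_trajectory(sp), list(spec = sp))
  })
}

# unit vector orthogonal to the rigid-body subspace of a point set (the
# component a superposition fit would absorb)
planted_unit_mode <- function(xyz, seed) {
  set.seed(seed)
  n <- nrow(xyz)
  cen <- sweep(xyz, 2, colMeans(xyz))
  basis <- cbind(
    rep(c(1, 0, 0), n), rep(c(0, 1, 0), n), rep(c(0, 0, 1), n),
    as.vector(t(cbind(0, -cen[, 3], cen[, 2]))),
    as.vector(t(cbind(cen[, 3], 0, -cen[, 1]))),
    as.vector(t(cbind(-cen[, 2], cen[, 1], 0))))
  Q <- qr.Q(qr(basis))
  v <- stats::rnorm(3 * n)
  v <- v - Q %*% crossprod(Q, v)
  as.vector(v / sqrt(sum(v^2)))
}

all_ca_selection <- function(top) {
  ca_selection(unique(top$atoms$resno[top$atoms$name == "CA"]))
}

# a small arbitrary protein-like topology built in code: n atoms scattered
# in a ball, all carbon, one residue each
scatter_topology <- function(n, seed = 1, radius = 4, resid = "ALA") {
  set.seed(seed)
  xyz <- matrix(stats::rnorm(3 * n, 0, radius), n, 3)
  at <- data.frame(eleno = seq_len(n), name = "CA", element = "C",
                   resno = seq_len(n), resid = resid, chain = "A",
                   stringsAsFactors = FALSE)
  topology(at, xyz = xyz)
}

# topology with explicit atoms: df columns name, element, resno, resid,
# chain + coordinate matrix
make_topology <- function(df, xyz) {
  df$eleno <- seq_len(nrow(df))
  suppressWarnings(topology(df[, c("eleno", "name", "element", "resno",
                                   "resid", "chain")], xyz = xyz))
}

static_trajectory <- function(top, n_frames = 1, box = c(100, 100, 100)) {
  trajectory(matrix(rep(as.vector(t(top$xyz)), each = n_frames),
                    nrow = n_frames), box)
}

# independent regex oracle for motif scanning: anchored match of every
# substring of length 5..13
motif_oracle <- function(sequence, classes = c("CRAC", "CARC")) {
  pats <- c(CRAC = "^[LV].{1,5}Y.{1,5}[KR]$",
            CARC = "^[KR].{1,5}[YF].{1,5}[LV]$")
  n <- nchar(sequence)
  rows <- list()
  for (cl in classes) {
    for (s in seq_len(n)) {
      for (e in (s + 4):min(n, s + 12)) {
        if (e > n) next
        sub <- substr(sequence, s, e)
        if (grepl(pats[cl], sub, perl = TRUE)) {
          rows[[length(rows) + 1]] <- data.frame(class = cl, start = s,
                                                 end = e)
        }
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(class = character(), start = integer(),
                      end = integer()))
  }
  out <- do.call(rbind, rows)
  out[order(out$start, out$end, out$class), ]
}

random_aa <- function(n, seed) {
  set.seed(seed)
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n,
               replace = TRUE), collapse = "")
}
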