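# Composite analysis pipeline: six probes + gates + cholesterol mapping +
# PCA on one trajectory, with a machine-readable summary.

#' Assemble a run configuration
#'
#' @param trajectory Path to a trajectory file, or a [trajectory()].
#' @param topology Path to a topology PDB, or a [topology()].
#' @param preset Preset name (`"hdat"`, `"hsert"`) or preset file path.
#' @param thresholds A [default_state_thresholds()] list.
#' @param voxel,enrichment,contact Occupancy-grid parameters.
#' @param sasa_points Sphere points per atom for the SASA probes.
#' @param run_pca Fit and project a PCA model (logical).
#' @param out_dir Output directory, or `NULL` for no file output.
#' @param seed Seed recorded with the outputs (the pipeline itself draws no
#'   random numbers).
#' @return Object of class `RunConfig`. Unknown extra arguments are
#'   rejected.
#' @export
run_config <- function(trajectory, topology, preset = "hdat",
                       thresholds = default_state_thresholds(),
                       voxel = 1, enrichment = 3, contact = 6,
                       sasa_points = 960, run_pca = TRUE, out_dir = NULL,
                       seed = NA) {
  structure(list(trajectory = trajectory, topology = topology,
                 preset = preset, thresholds = thresholds, voxel = voxel,
                 enrichment = enrichment, contact = contact,
                 sasa_points = sasa_points, run_pca = run_pca,
                 out_dir = out_dir, seed = seed),
            class = "RunConfig")
}

#' Run the full trajectory-analysis pipeline
#'
#' Computes the six transition probes, calls the inward state, monitors the
#' gate pairs (skipped with a note when the topology lacks the side-chain
#' types), builds the cholesterol occupancy grid, detects binding sites and
#' their occupancy fractions and bound traces, and optionally fits/projects
#' a PCA model. When `config$out_dir` is set, writes the probe table (CSV),
#' site list (JSON), occupancy grid (OpenDX), summary (JSON) and the
#' serialized configuration alongside the package version.
#'
#' @param config A [run_config()].
#' @return List: `probes`, `state`, `gates`, `grid`, `sites`,
#'   `site_fractions`, `bound_traces`, `pca`, `summary`.
#' @export
run_pipeline <- function(config) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(mp_error("pipeline", "stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }
  top <- stage("topology", {
    if (inherits(config$topology, "Topology")) config$topology else
      read_topology(config$topology)
  })
  traj <- stage("trajectory", {
    if (inherits(config$trajectory, "Trajectory")) config$trajectory else
      read_trajectory(config$trajectory, top)
  })
  presets <- stage("presets", load_selection_presets(config$preset))
  thr <- config$thresholds
  probes <- stage("probes", {
    list(
      tm5_rmsd = tm5_rmsd(traj, top, presets, thresholds = thr),
      helicity = helicity(traj, top, presets$tm5_ic_half, thresholds = thr),
      kink = kink_angle(traj, top, presets$tm5_full, presets$tm5_hinge,
                        thresholds = thr)$series,
      water = water_count(traj, top, selection(presets$na2_site),
                          thresholds = thr),
      sasa_ic = sasa_series(traj, top, selection(presets$ic_exit_path),
                            name = "sasa_ic", n_points = config$sasa_points,
                            thresholds = thr),
      sasa_t = sasa_series(traj, top, selection(presets$t_probe),
                           name = "sasa_t", n_points = config$sasa_points,
                           thresholds = thr))
  })
  state <- stage("state", call_state(probes, thr))
  gates <- tryCatch(gate_distances(traj, top, presets$gates),
                    error = function(e) {
                      structure(list(), skipped = conditionMessage(e))
                    })
  has_chol <- any(top$residues$class == "cholesterol-like")
  grid <- sites <- NULL
  fractions <- list()
  traces <- list()
  if (has_chol) {
    grid <- stage("occupancy", build_occupancy_grid(
      traj, top, ca_selection(unique(top$atoms$resno[protein_ca(top)])),
      voxel = config$voxel))
    sites <- stage("sites", detect_sites(grid, top,
                                         enrichment = config$enrichment,
                                         contact = config$contact))
    for (s in sites) {
      if (length(s$resno) == 0) next
      fractions[[sprintf("site%d", s$id)]] <-
        site_occupancy_fraction(traj, top, s)
    }
    if (length(sites) > 0 && length(sites[[1]]$resno) > 0) {
      lres <- lipid_residues(top)
      take <- lres[seq_len(min(2, length(lres)))]
      traces <- lapply(take, function(r) {
        bound_trace(traj, top, top$residues$resno[r], sites[[1]])
      })
    }
  }
  pca_out <- NULL
  if (isTRUE(config$run_pca) && traj$nframes >= 2) {
    pca_out <- stage("pca", {
      core <- intersect(presets$pca_core, top$atoms$resno[protein_ca(top)])
      model <- fit_pca(traj, top, ca_selection(core))
      proj <- project(traj, model, 1, top)
      list(model = model, projection = proj)
    })
  }
  summary <- list(
    package_version = as.character(utils::packageVersion("memprobe")),
    n_frames = traj$nframes,
    transition = state$transition,
    onset_frame = state$onset_frame,
    transition_fraction = state$fraction,
    gates_skipped = attr(gates, "skipped"),
    n_sites = length(sites),
    site_occupancy_fractions = fractions,
    pc1_cosine_content = if (is.null(pca_out)) NULL else
      pca_out$projection$cosine_content,
    seed = config$seed)
  if (!is.null(config$out_dir)) {
    d <- config$out_dir
    dir.create(d, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(probe_table(probes),
                     file.path(d, "probes.csv"), row.names = FALSE)
    jsonlite::write_json(summary, file.path(d, "summary.json"),
                         auto_unbox = TRUE, digits = NA, na = "null",
                         pretty = TRUE)
    if (!is.null(grid)) write_dx(grid, file.path(d, "occupancy.dx"))
    if (!is.null(sites)) {
      jsonlite::write_json(lapply(sites, function(s) {
        list(id = s$id, centroid = s$centroid, resno = s$resno,
             peak_enrichment = s$peak_enrichment)
      }), file.path(d, "sites.json"), digits = NA, auto_unbox = TRUE)
    }
    cfg <- config
    cfg$trajectory <- if (is.character(cfg$trajectory)) cfg$trajectory else
      "<in-memory>"
    cfg$topology <- if (is.character(cfg$topology)) cfg$topology else
      "<in-memory>"
    cfg$thresholds <- unclass(cfg$thresholds)
    yaml::write_yaml(c(unclass(cfg),
                       list(package_version = summary$package_version)),
                     file.path(d, "config.yaml"))
  }
  list(probes = probes, state = state, gates = gates, grid = grid,
       sites = sites, site_fractions = fractions, bound_traces = traces,
       pca = pca_out, summary = summary)
}

#' Membrane composition summary from lipid counts
#'
#' Cholesterol mole percentage and POPC:CHOL ratio implied by per-species
#' lipid counts of a bilayer, as used to describe the coarse-grain systems
#' (301 POPC + 74 CHOL, nominally 20% cholesterol at 4:1).
#'
#' @param popc,chol Lipid counts.
#' @return List: `chol_pct` (mole percent), `ratio` (POPC per CHOL),
#'   `chol_pct_rounded`, `ratio_rounded`.
#' @export
membrane_composition <- function(popc, chol) {
  pct <- 100 * chol / (popc + chol)
  list(chol_pct = pct, ratio = popc / chol,
       chol_pct_rounded = round(pct), ratio_rounded = round(popc / chol))
}
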