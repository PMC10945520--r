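# End-to-end orchestration: simulate (or load) -> contacts/diffusion ->
# occupancy -> frame selection -> geometry, with a reproducible manifest.

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order on a synthetic system
#' (or user-supplied inputs), writing TSV tables and density grids into
#' `out_dir` together with a manifest (parameters, seed, output MD5
#' checksums).  Identical config and seed give identical manifests.
#'
#' @param config named list (or path to a YAML file) with entries:
#'   \describe{
#'     \item{synthetic}{arguments for [sl_synthetic_config()] (the default
#'       input source).}
#'     \item{stages}{character vector among `"contacts"`, `"diffusion"`,
#'       `"occupancy"`, `"selection"`, `"geometry"` (default: all).}
#'     \item{contact_cutoff, shell_cutoff, proximity_cutoff}{cutoffs in
#'       Angstrom (defaults 4, 4, 3).}
#'     \item{spacing, threshold}{occupancy grid spacing (1 A) and
#'       occupancy threshold (0.4).}
#'     \item{n_frames_select, per_traj_cap}{frame-selection size (100) and
#'       per-trajectory cap (0.4).}
#'     \item{window}{diffusion fit window fractions (c(0.1, 0.5)).}
#'   }
#' @param out_dir output directory (created if needed).
#' @param seed integer seed for the synthetic stage.
#' @return the manifest, invisibly (list with `outputs`, `parameters`,
#'   `checksums`).
#' @export
run_pipeline <- function(config = list(), out_dir, seed = 1L) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- config$stages %||%
    c("contacts", "diffusion", "occupancy", "selection", "geometry")
  p <- list(
    contact_cutoff = config$contact_cutoff %||% 4,
    shell_cutoff = config$shell_cutoff %||% 4,
    proximity_cutoff = config$proximity_cutoff %||% 3,
    spacing = config$spacing %||% 1,
    threshold = config$threshold %||% 0.4,
    n_frames_select = config$n_frames_select %||% 100L,
    per_traj_cap = config$per_traj_cap %||% 0.4,
    window = config$window %||% c(0.1, 0.5),
    gap_tolerance = config$gap_tolerance %||% 0L)

  outputs <- character()
  add_out <- function(path) outputs <<- c(outputs, path)
  fail_stage <- function(stage, e) {
    file.create(file.path(out_dir, paste0(stage, ".failed")))
    stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
  }

  # --- input: synthetic simulation
  cfg <- do.call(sl_synthetic_config,
                 c(config$synthetic %||% list(), list(seed = seed)))
  sim <- simulate_bilayer(cfg, seed = seed)
  traj <- sim$trajectory
  topo <- sim$topology

  top_path <- file.path(out_dir, "topology.pdb")
  write_topology_pdb(topo, frame_coords(traj, 0L), top_path,
                     box = traj$box[1, ])
  add_out(top_path)
  lab_path <- file.path(out_dir, "state_labels.tsv")
  write_state_labels(sim$labels, lab_path)
  add_out(lab_path)
  gt <- sim$ground_truth
  gt_path <- file.path(out_dir, "ground_truth.tsv")
  write_tsv(cbind(D_free = gt$D_free, gt$sites), gt_path)
  add_out(gt_path)

  grids <- list()
  if ("contacts" %in% stages) {
    tryCatch({
      cs <- contact_series(traj, topo, cutoff = p$contact_cutoff)
      st <- duration_stats(cs, gap_tolerance = p$gap_tolerance)
      st$n_lipids_exchanged <- exchange_counts(cs)$n_lipids
      path <- file.path(out_dir, "contact_stats.tsv")
      write_tsv(st, path); add_out(path)
    }, error = function(e) fail_stage("contacts", e))
  }

  if ("diffusion" %in% stages) {
    tryCatch({
      shells <- assign_shells(traj, topo, cutoff = p$shell_cutoff)
      rows <- list()
      for (set in c("first_shell", "bulk")) {
        ids <- shells[[set]]
        if (!length(ids)) next
        msd <- lateral_msd(traj, topo, ids, label = set)
        est <- fit_diffusion(msd, window = p$window)
        mpath <- file.path(out_dir, paste0("msd_", set, ".tsv"))
        write_tsv(as.data.frame(msd), mpath); add_out(mpath)
        rows[[set]] <- data.frame(
          set = set, n_lipids = length(ids),
          D_nm2_per_us = est$D_nm2_per_us, slope_A2_per_ns = est$slope_A2_per_ns,
          r_squared = est$r_squared,
          window_lo_ns = est$window_ns[1], window_hi_ns = est$window_ns[2])
      }
      path <- file.path(out_dir, "diffusion.tsv")
      write_tsv(do.call(rbind, rows), path); add_out(path)
    }, error = function(e) fail_stage("diffusion", e))
  }

  if ("occupancy" %in% stages) {
    tryCatch({
      geom <- grid_geometry(traj, topo, spacing = p$spacing)
      states <- setdiff(unique(sim$labels$state), "unassigned")
      sym_rows <- list()
      for (s in states) {
        fr <- state_frames(sim$labels, traj$id, s)
        g <- occupancy_grid(traj, topo, fr, geometry = geom,
                            cutoff = p$proximity_cutoff, state = s)
        grids[[s]] <- g
        gpath <- file.path(out_dir, paste0("occupancy_", s, ".dx"))
        write_grid(g, gpath); add_out(gpath)
        tg <- threshold_grid(g, p$threshold)
        tpath <- file.path(out_dir, paste0("sites_", s, ".dx"))
        write_grid(tg, tpath); add_out(tpath)
        sym <- c5_symmetry_correlation(g, sim$center[1:2],
                                       n_fold = cfg$n_subunits)
        sym_rows[[s]] <- data.frame(state = s,
                                    k = seq_along(sym$correlations),
                                    correlation = sym$correlations)
      }
      if (all(c("closed", "open") %in% names(grids))) {
        dg <- state_difference(grids[["open"]], grids[["closed"]])
        dpath <- file.path(out_dir, "difference_open_minus_closed.dx")
        write_grid(dg, dpath); add_out(dpath)
      }
      spath <- file.path(out_dir, "symmetry_correlations.tsv")
      write_tsv(do.call(rbind, sym_rows), spath); add_out(spath)
    }, error = function(e) fail_stage("occupancy", e))
  }

  if ("selection" %in% stages) {
    tryCatch({
      ref_state <- config$selection_state %||% "open"
      if (is.null(grids[[ref_state]])) {
        stopf("frame selection needs the occupancy stage (reference grid for state '%s')",
              ref_state)
      }
      fr <- state_frames(sim$labels, traj$id, ref_state)
      cand <- data.frame(traj_id = traj$id, frame = fr)
      ranked <- rank_frames(list(traj), topo, cand, grids[[ref_state]],
                            cutoff = p$proximity_cutoff)
      sel <- suppressWarnings(
        select_representative(ranked, n = p$n_frames_select,
                              per_traj_cap = p$per_traj_cap))
      path <- file.path(out_dir, "selected_frames.tsv")
      write_tsv(sel, path); add_out(path)
    }, error = function(e) fail_stage("selection", e))
  }

  if ("geometry" %in% stages) {
    tryCatch({
      axis <- define_pore_axis(topo, frame_coords(traj, 0L))
      states <- setdiff(unique(sim$labels$state), "unassigned")
      rows <- lapply(states, function(s) {
        fr <- state_frames(sim$labels, traj$id, s)
        data.frame(state = s, n_frames = length(fr),
                   penetration_fraction = penetration_fraction(
                     traj, topo, fr, axis, slab = "outer",
                     r_threshold = cfg$protein_radius))
      })
      path <- file.path(out_dir, "penetration.tsv")
      write_tsv(do.call(rbind, rows), path); add_out(path)
    }, error = function(e) fail_stage("geometry", e))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("statelipid")),
    seed = seed, stages = stages, parameters = p,
    synthetic = config$synthetic %||% list(),
    outputs = basename(outputs),
    checksums = as.list(tools::md5sum(outputs)))
  names(manifest$checksums) <- basename(outputs)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
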