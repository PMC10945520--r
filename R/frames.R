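# Representative-frame selection: rank frames by the correlation between
# their instantaneous lipid density and a reference occupancy grid, then
# pick the top frames under a per-trajectory cap.

#' Binary lipid density of a single frame on a reference geometry
#'
#' Applies the same whole-lipid proximity selection as [occupancy_grid()]
#' to one frame and marks voxels inside any selected lipid atom's sphere.
#' Averaging [frame_density()] over a state's frames reproduces that
#' state's [occupancy_grid()].
#'
#' @param trajectory an [sl_trajectory()].
#' @param topology matching [sl_topology()].
#' @param frame 0-based frame index.
#' @param geometry reference [sl_grid()] fixing origin/spacing/dims.
#' @param cutoff whole-lipid selection cutoff, Angstrom (default 3).
#' @return binary [sl_grid()].
#' @export
frame_density <- function(trajectory, topology, frame, geometry, cutoff = 3) {
  occupancy_grid(trajectory, topology, frames = frame, geometry = geometry,
                 cutoff = cutoff, state = "single_frame")
}

#' Correlation between two density grids
#'
#' Product-moment correlation over a voxel mask (default: union of nonzero
#' voxels of the two grids).
#'
#' @param grid_a,grid_b [sl_grid()]s with identical geometry.
#' @param mask optional logical array selecting voxels.
#' @return correlation coefficient in `[-1, 1]`.
#' @export
density_correlation <- function(grid_a, grid_b, mask = NULL) {
  if (!grid_compatible(grid_a, grid_b)) {
    stopf("grids differ in origin, spacing or dimensions")
  }
  mask <- mask %||% (grid_a$values != 0 | grid_b$values != 0)
  va <- grid_a$values[mask]
  vb <- grid_b$values[mask]
  if (length(va) < 2 || stats::sd(va) == 0 || stats::sd(vb) == 0) {
    stopf("correlation undefined: zero variance over the mask")
  }
  stats::cor(va, vb)
}

#' Correlate every candidate frame against a reference density
#'
#' @param trajectories list of [sl_trajectory()] objects.
#' @param topology shared [sl_topology()].
#' @param frames data.frame with columns `traj_id`, `frame` naming the
#'   candidate frames (e.g. one state's frames from an
#'   [sl_state_labels()] table).
#' @param reference_grid reference occupancy [sl_grid()].
#' @param cutoff whole-lipid selection cutoff, Angstrom.
#' @return data.frame `traj_id`, `frame`, `correlation` (NA where the
#'   frame density has zero variance on the mask).
#' @export
rank_frames <- function(trajectories, topology, frames, reference_grid,
                        cutoff = 3) {
  ids <- vapply(trajectories, `[[`, "", "id")
  corr <- rep(NA_real_, nrow(frames))
  for (i in seq_len(nrow(frames))) {
    tr <- trajectories[[match(frames$traj_id[i], ids)]]
    fd <- frame_density(tr, topology, frames$frame[i], reference_grid,
                        cutoff)
    corr[i] <- tryCatch(density_correlation(fd, reference_grid),
                        error = function(e) NA_real_)
  }
  data.frame(traj_id = frames$traj_id, frame = frames$frame,
             correlation = corr, stringsAsFactors = FALSE)
}

#' Select representative frames under a per-trajectory cap
#'
#' Frames are sorted by correlation (descending; ties broken by ascending
#' trajectory id, then frame index) and accepted greedily, skipping any
#' frame whose trajectory already contributed `floor(per_traj_cap * n)`
#' accepted frames.  Selection stops at `n` frames or exhaustion (with a
#' warning).
#'
#' @param ranked data.frame from [rank_frames()] (columns `traj_id`,
#'   `frame`, `correlation`; NA correlations are dropped).
#' @param n number of frames to select (default 100).
#' @param per_traj_cap maximum fraction of the `n` selected frames allowed
#'   from a single trajectory (default 0.4).
#' @return data.frame `rank`, `traj_id`, `frame`, `correlation`.
#' @export
select_representative <- function(ranked, n = 100L, per_traj_cap = 0.4) {
  if (n <= 0) stopf("n must be positive")
  if (per_traj_cap <= 0 || per_traj_cap > 1) {
    stopf("per_traj_cap must be in (0, 1]")
  }
  ranked <- ranked[!is.na(ranked$correlation), , drop = FALSE]
  ord <- order(-ranked$correlation, ranked$traj_id, ranked$frame)
  ranked <- ranked[ord, , drop = FALSE]
  cap <- max(1L, floor(per_traj_cap * n))
  taken <- integer(0)
  counts <- integer(0)
  for (i in seq_len(nrow(ranked))) {
    tid <- ranked$traj_id[i]
    k <- counts[tid]
    if (is.na(k)) k <- 0L
    if (k >= cap) next
    counts[tid] <- k + 1L
    taken <- c(taken, i)
    if (length(taken) == n) break
  }
  if (length(taken) < n) {
    warnf("only %d of %d requested frames available under the %d-frame cap",
          length(taken), n, cap)
  }
  out <- ranked[taken, , drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}
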