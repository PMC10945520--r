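# State-classified lipid occupancy density grids: whole-lipid proximal
# selection, voxel occupancy fractions, thresholding, state differences and
# five-fold symmetry analysis.

#' Select whole lipids proximal to the protein surface
#'
#' A lipid qualifies iff any of its atoms lies within `cutoff` (minimum
#' image) of any protein atom in the frame; the ids of qualifying whole
#' lipids are returned, so all their atoms can be used downstream.
#'
#' @param trajectory an [sl_trajectory()].
#' @param topology matching [sl_topology()].
#' @param frame 0-based frame index.
#' @param cutoff proximity cutoff, Angstrom (default 3).
#' @return sorted integer vector of lipid molecule ids.
#' @export
select_proximal_lipids <- function(trajectory, topology, frame, cutoff = 3) {
  check_consistent(trajectory, topology)
  a <- topology$atoms
  fr <- frame_coords(trajectory, frame)
  pro <- which(a$kind == "protein")
  lip <- which(a$kind == "lipid")
  if (!length(lip)) return(integer())
  d2 <- cross_dist2(fr[lip, , drop = FALSE], fr[pro, , drop = FALSE],
                    trajectory$box[frame + 1L, ])
  near <- apply(d2, 1, min) <= cutoff^2
  sort(unique(a$lipid_id[lip][near]))
}

#' Default grid geometry covering the protein plus a margin
#'
#' @param trajectory,topology system definition; the protein bounding box
#'   of frame 0 is used.
#' @param spacing voxel spacing, Angstrom.
#' @param margin padding beyond the protein bounding box, Angstrom.
#' @return an empty [sl_grid()] with the chosen geometry.
#' @export
grid_geometry <- function(trajectory, topology, spacing = 1, margin = 8) {
  fr <- frame_coords(trajectory, 0L)
  pro <- protein_idx(topology)
  lo <- apply(fr[pro, , drop = FALSE], 2, min) - margin
  hi <- apply(fr[pro, , drop = FALSE], 2, max) + margin
  dims <- pmax(ceiling((hi - lo) / spacing) + 1L, 1L)
  sl_grid(array(0, dims), lo, spacing)
}

# mark voxels whose centres fall inside atom spheres; returns logical array
voxelize_atoms <- function(coords, radii, geom) {
  d <- dim(geom$values)
  occ <- array(FALSE, d)
  sp <- geom$spacing
  for (i in seq_len(nrow(coords))) {
    r <- radii[i]
    ctr <- (coords[i, ] - geom$origin) / sp + 1     # fractional voxel index
    lo <- pmax(ceiling(ctr - r / sp), 1L)
    hi <- pmin(floor(ctr + r / sp), d)
    if (any(lo > hi)) next
    ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
    dx2 <- (geom$origin[1] + (ix - 1) * sp - coords[i, 1])^2
    dy2 <- (geom$origin[2] + (iy - 1) * sp - coords[i, 2])^2
    dz2 <- (geom$origin[3] + (iz - 1) * sp - coords[i, 3])^2
    inside <- outer(outer(dx2, dy2, "+"), dz2, "+") <= r^2
    occ[ix, iy, iz] <- occ[ix, iy, iz, drop = FALSE] | inside
  }
  occ
}

#' Lipid occupancy density grid over a set of frames
#'
#' For each frame, whole lipids within `cutoff` of the protein surface are
#' selected and every voxel whose centre lies inside any selected lipid
#' atom's sphere (radius = the atom's van der Waals radius) is marked
#' occupied.  The grid value is the fraction of frames in which the voxel
#' was occupied, so values lie in `[0, 1]` and grids from disjoint frame
#' subsets combine as frame-count-weighted averages.
#'
#' @param trajectory an [sl_trajectory()].
#' @param topology matching [sl_topology()].
#' @param frames 0-based frame indices (typically one state's frames from
#'   [state_frames()]).
#' @param geometry an [sl_grid()] defining origin/spacing/dims (default
#'   from [grid_geometry()]).
#' @param cutoff whole-lipid selection cutoff, Angstrom (default 3).
#' @param state optional state label recorded in the grid metadata.
#' @return an [sl_grid()] of occupancy fractions.
#' @export
occupancy_grid <- function(trajectory, topology, frames,
                           geometry = NULL, cutoff = 3, state = NA_character_) {
  if (!length(frames)) {
    stopf("empty frame set for state filter '%s'", state)
  }
  check_consistent(trajectory, topology)
  geometry <- geometry %||% grid_geometry(trajectory, topology)
  a <- topology$atoms
  acc <- array(0, dim(geometry$values))
  for (fr0 in frames) {
    ids <- select_proximal_lipids(trajectory, topology, fr0, cutoff)
    if (length(ids)) {
      rows <- which(a$kind == "lipid" & a$lipid_id %in% ids)
      fr <- frame_coords(trajectory, fr0)
      acc <- acc + voxelize_atoms(fr[rows, , drop = FALSE],
                                  a$radius[rows], geometry)
    }
  }
  sl_grid(acc / length(frames), geometry$origin, geometry$spacing,
          meta = list(state = state, n_frames = length(frames),
                      cutoff = cutoff, traj_id = trajectory$id,
                      condition = trajectory$condition))
}

#' Threshold an occupancy grid into a binary binding-site grid
#'
#' Voxels are kept iff their occupancy fraction is at least `level`
#' (inclusive).
#'
#' @param grid an occupancy [sl_grid()].
#' @param level occupancy threshold in `[0, 1]` (default 0.4).
#' @return binary [sl_grid()] (values 0/1).
#' @export
threshold_grid <- function(grid, level = 0.4) {
  if (level < 0 || level > 1) stopf("threshold level must be in [0, 1]")
  sl_grid((grid$values >= level) * 1, grid$origin, grid$spacing,
          meta = c(grid$meta, list(threshold = level)))
}

#' Voxelwise difference between two state grids
#'
#' @param grid_a,grid_b [sl_grid()]s with identical geometry.
#' @return [sl_grid()] of `A - B`; metadata records the operand states.
#' @export
state_difference <- function(grid_a, grid_b) {
  if (!grid_compatible(grid_a, grid_b)) {
    stopf("grids differ in origin, spacing or dimensions")
  }
  sl_grid(grid_a$values - grid_b$values, grid_a$origin, grid_a$spacing,
          meta = list(state_a = grid_a$meta$state %||% NA,
                      state_b = grid_b$meta$state %||% NA))
}

# trilinear interpolation of grid values at arbitrary points (outside -> 0)
trilinear_sample <- function(grid, pts) {
  d <- dim(grid$values)
  f <- sweep(pts, 2, grid$origin) / grid$spacing + 1   # fractional index
  i0 <- floor(f)
  w <- f - i0
  val <- numeric(nrow(pts))
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    ix <- i0[, 1] + cx; iy <- i0[, 2] + cy; iz <- i0[, 3] + cz
    ok <- ix >= 1 & ix <= d[1] & iy >= 1 & iy <= d[2] & iz >= 1 & iz <= d[3]
    if (!any(ok)) next
    wt <- (cx * w[, 1] + (1 - cx) * (1 - w[, 1])) *
          (cy * w[, 2] + (1 - cy) * (1 - w[, 2])) *
          (cz * w[, 3] + (1 - cz) * (1 - w[, 3]))
    lin <- ix[ok] + d[1] * (iy[ok] - 1L) + d[1] * d[2] * (iz[ok] - 1L)
    val[ok] <- val[ok] + wt[ok] * grid$values[lin]
  }
  val
}

# rotate a grid about a z-axis through `center` by `angle` (radians),
# trilinear resampling
rotate_grid_z <- function(grid, angle, center) {
  d <- dim(grid$values)
  ax <- grid_axis(grid, 1); ay <- grid_axis(grid, 2); az <- grid_axis(grid, 3)
  pts <- as.matrix(expand.grid(x = ax, y = ay, z = az))
  # inverse rotation of the sampling points
  ca <- cos(-angle); sa <- sin(-angle)
  dx <- pts[, 1] - center[1]; dy <- pts[, 2] - center[2]
  src <- cbind(center[1] + ca * dx - sa * dy,
               center[2] + sa * dx + ca * dy,
               pts[, 3])
  sl_grid(array(trilinear_sample(grid, src), d), grid$origin, grid$spacing,
          meta = grid$meta)
}

#' Five-fold symmetry correlation and symmetrisation of a density grid
#'
#' Correlates the grid with its rotations by k * 360/n degrees
#' (k = 1 .. n-1) about the pore axis (z through `center`), using
#' trilinear resampling and restricting to the union of nonzero voxels of
#' the two operands.  The symmetrised grid is the mean over all n
#' rotations.
#'
#' @param grid an [sl_grid()].
#' @param center length-2 or -3 (x, y) position of the symmetry axis,
#'   Angstrom.
#' @param n_fold symmetry order (default 5).
#' @return list with `correlations` (length `n_fold - 1`) and
#'   `symmetrized` ([sl_grid()]).
#' @export
c5_symmetry_correlation <- function(grid, center, n_fold = 5L) {
  if (length(center) < 2 || any(!is.finite(center[1:2]))) {
    stopf("degenerate symmetry axis")
  }
  rots <- lapply(seq_len(n_fold - 1L), function(k) {
    rotate_grid_z(grid, 2 * pi * k / n_fold, center)
  })
  cors <- vapply(rots, function(rg) {
    mask <- grid$values != 0 | rg$values != 0
    if (sum(mask) < 2) return(NA_real_)
    stats::cor(grid$values[mask], rg$values[mask])
  }, numeric(1))
  sym <- grid$values
  for (rg in rots) sym <- sym + rg$values
  list(correlations = cors,
       symmetrized = sl_grid(sym / n_fold, grid$origin, grid$spacing,
                             meta = grid$meta))
}
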