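# In-memory data model shared by all analysis stages.

#' Construct a topology
#'
#' A topology describes every atom (or coarse bead) of the system: its
#' residue, chain/subunit, whether it belongs to the protein or to a lipid,
#' and — for lipid atoms — the lipid molecule it belongs to.  Residue
#' numbering is taken verbatim from the input; frames are indexed 0-based
#' throughout the package.
#'
#' @param atoms data.frame with columns `eleno` (atom serial), `elety`
#'   (atom/bead name), `resid` (residue number), `resname`, `chain`,
#'   `kind` (`"protein"` or `"lipid"`), `lipid_id` (integer molecule id for
#'   lipid atoms, `NA` for protein) and `radius` (van der Waals radius,
#'   Angstrom).
#' @return object of class `sl_topology`.
#' @export
sl_topology <- function(atoms) {
  required <- c("eleno", "elety", "resid", "resname", "chain",
                "kind", "lipid_id", "radius")
  missing <- setdiff(required, names(atoms))
  if (length(missing)) {
    stopf("topology is missing columns: %s", paste(missing, collapse = ", "))
  }
  if (!all(atoms$kind %in% c("protein", "lipid"))) {
    stopf("atom kind must be 'protein' or 'lipid'")
  }
  bad <- atoms$kind == "lipid" & is.na(atoms$lipid_id)
  if (any(bad)) stopf("%d lipid atoms lack a lipid molecule id", sum(bad))
  if (any(!is.finite(atoms$radius)) || any(atoms$radius <= 0)) {
    stopf("van der Waals radii must be positive")
  }
  rownames(atoms) <- NULL
  structure(list(atoms = atoms), class = "sl_topology")
}

#' @export
print.sl_topology <- function(x, ...) {
  a <- x$atoms
  cat(sprintf(
    "<sl_topology> %d atoms: %d protein (%d chains), %d lipid atoms (%d molecules)\n",
    nrow(a), sum(a$kind == "protein"),
    length(unique(a$chain[a$kind == "protein"])),
    sum(a$kind == "lipid"),
    length(unique(a$lipid_id[a$kind == "lipid"]))))
  invisible(x)
}

n_lipids <- function(topology) {
  length(unique(stats::na.omit(topology$atoms$lipid_id)))
}

protein_idx <- function(topology) which(topology$atoms$kind == "protein")
lipid_idx   <- function(topology) which(topology$atoms$kind == "lipid")

#' Construct a trajectory
#'
#' @param coords numeric array `n_atoms x 3 x n_frames` of wrapped
#'   coordinates in Angstrom.
#' @param box per-frame box vectors: `n_frames x 3` matrix or length-3
#'   vector recycled to all frames (Angstrom).
#' @param dt time between frames in nanoseconds.
#' @param id trajectory identifier string.
#' @param condition optional condition tag (e.g. `"resting"`,
#'   `"activating"`).
#' @param unwrapped optional unwrapped coordinates, same shape as `coords`
#'   (needed for mean-square-displacement analysis; reconstructed from the
#'   wrapped coordinates on demand if absent).
#' @return object of class `sl_trajectory`.
#' @export
sl_trajectory <- function(coords, box, dt, id = "traj", condition = NA_character_,
                          unwrapped = NULL) {
  if (length(dim(coords)) != 3 || dim(coords)[2] != 3) {
    stopf("coords must be an n_atoms x 3 x n_frames array")
  }
  nf <- dim(coords)[3]
  if (is.null(dim(box))) box <- matrix(box, nf, 3, byrow = TRUE)
  if (nrow(box) != nf) stopf("box must have one row per frame")
  if (!is.finite(dt) || dt <= 0) stopf("dt must be positive (ns)")
  if (!is.null(unwrapped) && !identical(dim(unwrapped), dim(coords))) {
    stopf("unwrapped coordinates must match coords in shape")
  }
  structure(list(coords = coords, box = box, dt = dt, id = id,
                 condition = condition, unwrapped = unwrapped),
            class = "sl_trajectory")
}

#' @export
print.sl_trajectory <- function(x, ...) {
  cat(sprintf("<sl_trajectory> '%s': %d atoms x %d frames, dt = %g ns%s\n",
              x$id, dim(x$coords)[1], dim(x$coords)[3], x$dt,
              if (is.na(x$condition)) "" else paste0(", condition = ", x$condition)))
  invisible(x)
}

n_frames <- function(trajectory) dim(trajectory$coords)[3]

frame_coords <- function(trajectory, frame) {
  # frame is 0-based
  trajectory$coords[, , frame + 1L]
}

check_consistent <- function(trajectory, topology) {
  if (dim(trajectory$coords)[1] != nrow(topology$atoms)) {
    stopf("trajectory has %d atoms but topology has %d",
          dim(trajectory$coords)[1], nrow(topology$atoms))
  }
  invisible(TRUE)
}

#' Construct a state-label table
#'
#' Maps `(trajectory id, frame index)` to a discrete conformational state
#' label, standing in for Markov-state-model cluster assignments.  Frames
#' not present in the table are treated as `"unassigned"` downstream.
#'
#' @param df data.frame with columns `traj_id`, `frame` (0-based) and
#'   `state`.
#' @param vocabulary allowed state labels; `"unassigned"` is always
#'   permitted.
#' @return object of class `sl_state_labels` (a data.frame).
#' @export
sl_state_labels <- function(df, vocabulary = c("closed", "open")) {
  required <- c("traj_id", "frame", "state")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stopf("state label table is missing columns: %s",
          paste(missing, collapse = ", "))
  }
  vocabulary <- union(vocabulary, "unassigned")
  bad <- setdiff(unique(df$state), vocabulary)
  if (length(bad)) {
    stopf("unknown state label(s): %s (vocabulary: %s)",
          paste(bad, collapse = ", "), paste(vocabulary, collapse = ", "))
  }
  dup <- duplicated(df[c("traj_id", "frame")])
  if (any(dup)) {
    stopf("duplicate (traj_id, frame) assignments: %d rows", sum(dup))
  }
  df <- df[c("traj_id", "frame", "state")]
  rownames(df) <- NULL
  structure(df, class = c("sl_state_labels", "data.frame"),
            vocabulary = vocabulary)
}

#' Frames of one trajectory carrying a given state label
#'
#' @param labels an [sl_state_labels()] table.
#' @param traj_id trajectory identifier.
#' @param state state label to select.
#' @return sorted integer vector of 0-based frame indices.
#' @export
state_frames <- function(labels, traj_id, state) {
  sort(labels$frame[labels$traj_id == traj_id & labels$state == state])
}

#' Construct a volumetric grid
#'
#' A regular 3D grid of scalar values (typically occupancy fractions in
#' `[0, 1]`) with an origin and isotropic spacing, both in Angstrom.  The
#' voxel at index `(i, j, k)` (1-based) has its centre at
#' `origin + spacing * (c(i, j, k) - 1)`.
#'
#' @param values numeric 3D array.
#' @param origin length-3 numeric, centre of the first voxel (Angstrom).
#' @param spacing isotropic voxel spacing (Angstrom).
#' @param meta optional named list of metadata (state labels, operands...).
#' @return object of class `sl_grid`.
#' @export
sl_grid <- function(values, origin, spacing, meta = list()) {
  if (length(dim(values)) != 3) stopf("grid values must be a 3D array")
  if (!is.finite(spacing) || spacing <= 0) stopf("spacing must be positive")
  if (length(origin) != 3) stopf("origin must have 3 components")
  structure(list(values = values, origin = as.numeric(origin),
                 spacing = as.numeric(spacing), meta = meta),
            class = "sl_grid")
}

#' @export
print.sl_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<sl_grid> %d x %d x %d voxels, spacing %g A, origin (%g, %g, %g), range [%g, %g]\n",
    d[1], d[2], d[3], x$spacing, x$origin[1], x$origin[2], x$origin[3],
    min(x$values), max(x$values)))
  invisible(x)
}

grid_compatible <- function(a, b, tol = 1e-6) {
  identical(dim(a$values), dim(b$values)) &&
    max(abs(a$origin - b$origin)) < tol &&
    abs(a$spacing - b$spacing) < tol
}

#' Voxel-centre coordinates of a grid axis
#' @noRd
grid_axis <- function(grid, k) {
  grid$origin[k] + grid$spacing * (seq_len(dim(grid$values)[k]) - 1)
}
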