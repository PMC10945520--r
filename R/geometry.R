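# State-dependent geometric analyses around the pore axis: radial
# lipid-approach statistics, penetration probabilities, residue-lipid
# minimum distances, 2D landscape projections, and a geometric open/closed
# classifier for synthetic systems.

#' Define the pore axis of the protein
#'
#' The axis is the membrane normal (z by convention) through the protein
#' centre of geometry; leaflet slabs are z-intervals supplied by the
#' caller.
#'
#' @param topology an [sl_topology()].
#' @param coords n x 3 coordinate matrix of one frame.
#' @param slabs named list of length-2 z-intervals, Angstrom (e.g.
#'   `list(outer = c(10, 22), inner = c(-22, -10))`).
#' @return object of class `sl_pore_axis`: `origin` (length 3), `axis`
#'   (unit vector), `slabs`.
#' @export
define_pore_axis <- function(topology, coords,
                             slabs = list(outer = c(5, 25),
                                          inner = c(-25, -5))) {
  pro <- protein_idx(topology)
  if (length(pro) < 5) stopf("need at least 5 protein atoms to define an axis")
  origin <- colMeans(coords[pro, , drop = FALSE])
  structure(list(origin = as.numeric(origin), axis = c(0, 0, 1),
                 slabs = slabs), class = "sl_pore_axis")
}

# perpendicular distance of points to the axis (vertical axis assumed)
radial_dist <- function(pts, axis) {
  sqrt((pts[, 1] - axis$origin[1])^2 + (pts[, 2] - axis$origin[2])^2)
}

#' Minimum radial lipid distance from the pore axis within a slab
#'
#' Over lipid atoms whose z lies in the slab, the minimum perpendicular
#' distance to the pore axis; optionally resolved into azimuthal wedges of
#' `360 / n_sectors` degrees anchored at the first subunit.
#'
#' @param trajectory an [sl_trajectory()].
#' @param topology matching [sl_topology()].
#' @param frame 0-based frame index.
#' @param axis an [define_pore_axis()] result.
#' @param slab name of a slab in `axis$slabs`, or a length-2 z-interval.
#' @param n_sectors if > 0, return one minimum per azimuthal sector.
#' @return minimum radial distance in Angstrom (`NA` if no lipid atom lies
#'   in the slab), or a length-`n_sectors` vector.
#' @export
radial_min_distance <- function(trajectory, topology, frame, axis,
                                slab = "outer", n_sectors = 0L) {
  check_consistent(trajectory, topology)
  zint <- if (is.character(slab)) {
    if (!slab %in% names(axis$slabs)) stopf("unknown slab '%s'", slab)
    axis$slabs[[slab]]
  } else slab
  fr <- frame_coords(trajectory, frame)
  lip <- lipid_idx(topology)
  pts <- fr[lip, , drop = FALSE]
  sel <- pts[, 3] >= zint[1] & pts[, 3] <= zint[2]
  pts <- pts[sel, , drop = FALSE]
  if (n_sectors <= 0L) {
    if (!nrow(pts)) return(NA_real_)
    return(min(radial_dist(pts, axis)))
  }
  if (!nrow(pts)) return(rep(NA_real_, n_sectors))
  ang <- atan2(pts[, 2] - axis$origin[2], pts[, 1] - axis$origin[1]) %% (2 * pi)
  sector <- pmin(floor(ang / (2 * pi / n_sectors)) + 1L, n_sectors)
  r <- radial_dist(pts, axis)
  out <- rep(NA_real_, n_sectors)
  mins <- tapply(r, sector, min)
  out[as.integer(names(mins))] <- mins
  out
}

#' Fraction of frames in which lipids penetrate toward the pore axis
#'
#' @param trajectory an [sl_trajectory()].
#' @param topology matching [sl_topology()].
#' @param frames 0-based frame indices (typically one state's frames).
#' @param axis an [define_pore_axis()] result.
#' @param slab slab name or z-interval, as in [radial_min_distance()].
#' @param r_threshold radial threshold, Angstrom.
#' @return fraction of frames whose minimum radial lipid distance is at or
#'   below `r_threshold` (frames with no slab lipid count as
#'   non-penetrating).
#' @export
penetration_fraction <- function(trajectory, topology, frames, axis,
                                 slab = "outer", r_threshold) {
  if (!length(frames)) stopf("empty frame set")
  rmin <- vapply(frames, function(f) {
    radial_min_distance(trajectory, topology, f, axis, slab)
  }, numeric(1))
  mean(!is.na(rmin) & rmin <= r_threshold)
}

#' Minimum distance between one residue and any lipid atom
#'
#' @param trajectory an [sl_trajectory()].
#' @param topology matching [sl_topology()].
#' @param frame 0-based frame index, or a vector of frames (returns one
#'   distance per frame).
#' @param chain,resid residue identity.
#' @return minimum-image minimum distance(s), Angstrom.
#' @export
residue_lipid_min_distance <- function(trajectory, topology, frame,
                                       chain, resid) {
  check_consistent(trajectory, topology)
  a <- topology$atoms
  ratoms <- which(a$kind == "protein" & a$chain == chain & a$resid == resid)
  if (!length(ratoms)) stopf("no residue %s:%s in topology", chain, resid)
  lip <- lipid_idx(topology)
  if (!length(lip)) stopf("topology contains no lipid atoms")
  vapply(frame, function(f) {
    fr <- frame_coords(trajectory, f)
    sqrt(min(cross_dist2(fr[ratoms, , drop = FALSE],
                         fr[lip, , drop = FALSE],
                         trajectory$box[f + 1L, ])))
  }, numeric(1))
}

#' Per-state fraction of frames with a residue-lipid contact
#'
#' @param distances per-frame minimum distances (Angstrom).
#' @param states per-frame state labels, aligned with `distances`.
#' @param threshold contact threshold, Angstrom (default 3).
#' @return data.frame `state`, `fraction`, `n_frames`; states with zero
#'   frames are absent (flagged missing by omission).
#' @export
state_contact_fraction <- function(distances, states, threshold = 3) {
  if (length(distances) != length(states)) {
    stopf("distances and states must align per frame")
  }
  agg <- tapply(distances <= threshold, states, mean)
  cnt <- tapply(distances, states, length)
  data.frame(state = names(agg), fraction = as.numeric(agg),
             n_frames = as.integer(cnt), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Project a per-frame scalar onto a 2D collective-variable landscape
#'
#' Bins frames by their two collective-variable values and reports the
#' per-bin arithmetic mean of the scalar; empty bins carry `NA` and are
#' flagged.
#'
#' @param cv1,cv2 per-frame collective-variable values.
#' @param scalar per-frame scalar (e.g. residue-lipid minimum distance).
#' @param breaks1,breaks2 strictly increasing bin edges for each variable.
#' @return list of class `sl_landscape`: `mean` and `count` matrices
#'   (rows = cv1 bins), `breaks1`, `breaks2`, `empty` logical matrix.
#' @export
landscape_projection <- function(cv1, cv2, scalar, breaks1, breaks2) {
  if (any(diff(breaks1) <= 0) || any(diff(breaks2) <= 0)) {
    stopf("bin edges must be strictly increasing")
  }
  if (length(cv1) != length(scalar) || length(cv2) != length(scalar)) {
    stopf("cv and scalar series must align per frame")
  }
  b1 <- cut(cv1, breaks1, include.lowest = TRUE, labels = FALSE)
  b2 <- cut(cv2, breaks2, include.lowest = TRUE, labels = FALSE)
  ok <- !is.na(b1) & !is.na(b2)
  n1 <- length(breaks1) - 1L
  n2 <- length(breaks2) - 1L
  mn <- matrix(NA_real_, n1, n2)
  cnt <- matrix(0L, n1, n2)
  if (any(ok)) {
    idx <- (b2[ok] - 1L) * n1 + b1[ok]
    sums <- tapply(scalar[ok], idx, sum)
    ns <- tapply(scalar[ok], idx, length)
    cnt[as.integer(names(ns))] <- as.integer(ns)
    mn[as.integer(names(sums))] <- sums / ns
  }
  structure(list(mean = mn, count = cnt, breaks1 = breaks1,
                 breaks2 = breaks2, empty = cnt == 0L),
            class = "sl_landscape")
}

#' Geometric open/closed state classifier
#'
#' Classifies a frame as `"open"` iff the mean radial distance of the gate
#' atoms from the pore axis is at least `open_radius` (inclusive).  On
#' synthetic trajectories, whose gate beads move radially with the state
#' schedule, this recovers the generating schedule exactly.
#'
#' @param trajectory an [sl_trajectory()].
#' @param topology matching [sl_topology()].
#' @param frame 0-based frame index or vector of frames.
#' @param gate_idx atom row indices of the pore-lining gate atoms.
#' @param axis an [define_pore_axis()] result.
#' @param open_radius radius threshold, Angstrom.
#' @return character vector of `"open"` / `"closed"` labels.
#' @export
geometric_state_classifier <- function(trajectory, topology, frame, gate_idx,
                                       axis, open_radius = 4.5) {
  if (!length(gate_idx)) stopf("no gate atoms given")
  vapply(frame, function(f) {
    fr <- frame_coords(trajectory, f)
    r <- mean(radial_dist(fr[gate_idx, , drop = FALSE], axis))
    if (r >= open_radius) "open" else "closed"
  }, character(1))
}
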