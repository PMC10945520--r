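# Per-residue lipid contact series, contact-duration statistics and
# lipid-exchange counts.

#' Residue-lipid contact time series
#'
#' A protein residue and a lipid molecule are in contact in a frame iff the
#' minimum over all atom pairs of the minimum-image distance is at or below
#' the cutoff (default 4 Angstrom, all atoms).  The minimum-image
#' convention is applied in x, y and z for orthorhombic boxes.
#'
#' @param trajectory an [sl_trajectory()].
#' @param topology matching [sl_topology()].
#' @param cutoff interaction cutoff, Angstrom.
#' @param residues optional data.frame with columns `chain`, `resid`
#'   restricting the protein residues analysed (default: all).
#' @return object of class `sl_contact_series`: logical array
#'   `n_residues x n_lipids x n_frames` with residue (`"chain:resid"`) and
#'   lipid-id dimnames, plus `dt`, `cutoff`, `residues` (data.frame with
#'   chain, resid, resname) and `traj_id`.
#' @export
contact_series <- function(trajectory, topology, cutoff = 4,
                           residues = NULL) {
  check_consistent(trajectory, topology)
  if (cutoff <= 0) stopf("cutoff must be positive")
  a <- topology$atoms
  lip <- which(a$kind == "lipid")
  if (!length(lip)) stopf("topology contains no lipid atoms")

  pro <- which(a$kind == "protein")
  rkey <- paste0(a$chain[pro], ":", a$resid[pro])
  if (!is.null(residues)) {
    want <- paste0(residues$chain, ":", residues$resid)
    keep <- rkey %in% want
    pro <- pro[keep]
    rkey <- rkey[keep]
    if (!length(pro)) stopf("no protein atoms match the residue selection")
  }
  res_levels <- unique(rkey)
  res_fac <- factor(rkey, levels = res_levels)
  lip_ids <- sort(unique(a$lipid_id[lip]))
  lip_fac <- factor(a$lipid_id[lip], levels = lip_ids)

  # 0/1 aggregation matrices: atoms -> residues / lipid molecules
  Rm <- matrix(0, length(pro), length(res_levels))
  Rm[cbind(seq_along(pro), as.integer(res_fac))] <- 1
  Lm <- matrix(0, length(lip), length(lip_ids))
  Lm[cbind(seq_along(lip), as.integer(lip_fac))] <- 1

  nf <- n_frames(trajectory)
  out <- array(FALSE, c(length(res_levels), length(lip_ids), nf),
               dimnames = list(res_levels, lip_ids, NULL))
  c2 <- cutoff^2
  for (f in seq_len(nf)) {
    fr <- trajectory$coords[, , f]
    d2 <- cross_dist2(fr[pro, , drop = FALSE], fr[lip, , drop = FALSE],
                      trajectory$box[f, ])
    hit <- (d2 <= c2) * 1
    out[, , f] <- (crossprod(Rm, hit) %*% Lm) > 0
  }
  first <- match(res_levels, rkey)
  structure(list(
    contacts = out, dt = trajectory$dt, cutoff = cutoff,
    traj_id = trajectory$id,
    residues = data.frame(chain = a$chain[pro][first],
                          resid = a$resid[pro][first],
                          resname = a$resname[pro][first],
                          stringsAsFactors = FALSE)),
    class = "sl_contact_series")
}

#' @export
print.sl_contact_series <- function(x, ...) {
  d <- dim(x$contacts)
  cat(sprintf(
    "<sl_contact_series> '%s': %d residues x %d lipids x %d frames, cutoff %g A\n",
    x$traj_id, d[1], d[2], d[3], x$cutoff))
  invisible(x)
}

#' Per-residue contact-duration statistics
#'
#' For each (residue, lipid) pair, maximal runs of consecutive contact
#' frames are extracted; runs separated by at most `gap_tolerance`
#' non-contact frames are merged, with the gap counted into the duration.
#' The per-residue mean duration is the mean run length (in ns) over all
#' lipids.  Runs truncated by either trajectory end are counted at their
#' observed length and flagged as censored.
#'
#' @param series an [contact_series()] result.
#' @param gap_tolerance frames of lost contact tolerated inside one run.
#' @return data.frame (one row per residue) with columns `traj_id`,
#'   `chain`, `resid`, `resname`, `mean_duration_ns`, `n_runs`, `n_lipids`
#'   and `censored` (TRUE if any contributing run touches a trajectory
#'   end).
#' @export
duration_stats <- function(series, gap_tolerance = 0L) {
  ct <- series$contacts
  d <- dim(ct)
  res <- series$residues
  out <- data.frame(
    traj_id = series$traj_id, chain = res$chain, resid = res$resid,
    resname = res$resname, mean_duration_ns = 0, n_runs = 0L,
    n_lipids = 0L, censored = FALSE, stringsAsFactors = FALSE)
  for (r in seq_len(d[1])) {
    lens <- integer()
    cens <- logical()
    nlip <- 0L
    for (l in seq_len(d[2])) {
      x <- ct[r, l, ]
      if (!any(x)) next
      nlip <- nlip + 1L
      runs <- contact_runs(x, gap_tolerance)
      lens <- c(lens, runs$length)
      cens <- c(cens, runs$censored)
    }
    if (length(lens)) {
      out$mean_duration_ns[r] <- mean(lens) * series$dt
      out$n_runs[r] <- length(lens)
      out$n_lipids[r] <- nlip
      out$censored[r] <- any(cens)
    }
  }
  out
}

#' Per-residue lipid-exchange counts
#'
#' Number of distinct lipid molecules that contact each residue at least
#' once over the trajectory.
#'
#' @param series an [contact_series()] result.
#' @return data.frame with columns `traj_id`, `chain`, `resid`, `resname`,
#'   `n_lipids`.
#' @export
exchange_counts <- function(series) {
  ct <- series$contacts
  any_contact <- apply(ct, c(1, 2), any)
  res <- series$residues
  data.frame(traj_id = series$traj_id, chain = res$chain, resid = res$resid,
             resname = res$resname,
             n_lipids = as.integer(rowSums(any_contact)),
             stringsAsFactors = FALSE)
}

#' Aggregate per-trajectory contact statistics over an ensemble
#'
#' Residues are matched by `(chain, resid)` — or by `resid` alone when
#' `pool_subunits = TRUE`, so the subunits of a symmetric oligomer are
#' pooled as independent samples.
#'
#' @param stats_list list of [duration_stats()] (or [exchange_counts()])
#'   data.frames, one per trajectory.
#' @param value column to aggregate (default `"mean_duration_ns"`).
#' @param pool_subunits pool chains by residue number.
#' @return list with `ensemble` (per-residue mean, n, sd, se over
#'   trajectories/subunits) and `points` (all per-trajectory rows,
#'   retained).
#' @export
aggregate_ensemble <- function(stats_list, value = "mean_duration_ns",
                               pool_subunits = FALSE) {
  if (!length(stats_list)) stopf("empty list of per-trajectory statistics")
  pts <- do.call(rbind, stats_list)
  if (!value %in% names(pts)) stopf("no column '%s' to aggregate", value)
  key <- if (pool_subunits) {
    data.frame(resid = pts$resid)
  } else {
    data.frame(chain = pts$chain, resid = pts$resid)
  }
  agg <- stats::aggregate(pts[[value]], key, function(v) {
    c(mean = mean(v), n = length(v), sd = stats::sd(v))
  })
  ens <- cbind(agg[setdiff(names(agg), "x")], as.data.frame(agg$x))
  ens$se <- ens$sd / sqrt(ens$n)
  names(ens)[names(ens) == "mean"] <- value
  list(ensemble = ens, points = pts)
}
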