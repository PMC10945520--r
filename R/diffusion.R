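# Lateral lipid diffusion from the Einstein relation: MSD(t) -> 4 D t,
# computed for first-shell vs bulk lipid sets with the protein
# centre-of-mass contribution removed.

#' Partition lipids into first shell and bulk at the reference frame
#'
#' A lipid belongs to the first shell iff any of its atoms lies within
#' `cutoff` (minimum image) of any protein atom in the reference frame;
#' all other lipids are bulk.  Membership is fixed at that frame — the two
#' disjoint sets are not updated when lipids later exchange shells.
#'
#' @param trajectory an [sl_trajectory()].
#' @param topology matching [sl_topology()].
#' @param cutoff shell cutoff, Angstrom (default 4).
#' @param frame 0-based reference frame (default 0).
#' @return list with integer lipid-id vectors `first_shell` and `bulk`.
#' @export
assign_shells <- function(trajectory, topology, cutoff = 4, frame = 0L) {
  check_consistent(trajectory, topology)
  a <- topology$atoms
  fr <- frame_coords(trajectory, frame)
  pro <- which(a$kind == "protein")
  lip <- which(a$kind == "lipid")
  if (!length(lip)) stopf("topology contains no lipid atoms")
  d2 <- cross_dist2(fr[lip, , drop = FALSE], fr[pro, , drop = FALSE],
                    trajectory$box[frame + 1L, ])
  near <- apply(d2, 1, min) <= cutoff^2
  ids <- a$lipid_id[lip]
  first_shell <- sort(unique(ids[near]))
  all_ids <- sort(unique(ids))
  list(first_shell = first_shell,
       bulk = setdiff(all_ids, first_shell))
}

#' Unwrap lateral coordinates by nearest-image displacement accumulation
#' @noRd
unwrap_lateral <- function(xy, box2) {
  # xy: n_frames x n x 2 array (wrapped); returns same shape, unwrapped
  nf <- dim(xy)[1]
  out <- xy
  for (f in 2:nf) {
    d <- matrix(xy[f, , ] - xy[f - 1L, , ], ncol = 2)
    for (k in 1:2) {
      bk <- box2[k]
      if (is.finite(bk) && bk > 0) {
        raw <- d[, k]
        d[, k] <- raw - bk * round(raw / bk)
        # a physical step > box/2 is indistinguishable from a wrap
        if (any(abs(d[, k]) >= bk / 2 - 1e-9)) {
          stopf("unwrapping failed: per-frame displacement exceeds box/2")
        }
      }
    }
    out[f, , ] <- out[f - 1L, , ] + d
  }
  out
}

#' Lateral mean-square displacement of a lipid set
#'
#' Uses unwrapped coordinates (taken from the trajectory if present,
#' otherwise reconstructed by nearest-image displacement accumulation,
#' which fails loudly if any per-frame displacement exceeds half the box).
#' The lateral (x, y) displacement of the protein centre of geometry
#' relative to frame 0 is subtracted from every lipid position before
#' squaring, removing collective drift.  All sliding time origins are
#' averaged (computed exactly via FFT autocorrelation).
#'
#' @param trajectory an [sl_trajectory()].
#' @param topology matching [sl_topology()].
#' @param lipid_ids lipid molecule ids to average over (e.g. from
#'   [assign_shells()]).
#' @param remove_protein_com subtract the protein lateral COM displacement
#'   (default TRUE).
#' @param label set label stored on the curve (`"first_shell"`, `"bulk"`,
#'   ...).
#' @return object of class `sl_msd`: data.frame columns `lag_ns`,
#'   `msd_A2`, `n_pairs` plus attributes `dt` and `label`.  `msd_A2[1]`
#'   is the zero-lag point (0 by construction).
#' @export
lateral_msd <- function(trajectory, topology, lipid_ids,
                        remove_protein_com = TRUE, label = "lipids") {
  check_consistent(trajectory, topology)
  if (!length(lipid_ids)) stopf("empty lipid set")
  a <- topology$atoms
  nf <- n_frames(trajectory)
  src <- trajectory$unwrapped
  lip_rows <- which(a$kind == "lipid" & a$lipid_id %in% lipid_ids)
  if (!length(lip_rows)) stopf("no atoms for the requested lipid ids")

  # per-lipid centre of geometry, frames x lipids x 2 (lateral)
  nlip <- length(lipid_ids)
  com <- array(NA_real_, c(nf, nlip, 2))
  fac <- factor(a$lipid_id[lip_rows], levels = lipid_ids)
  for (f in seq_len(nf)) {
    fr <- trajectory$coords[, , f]
    if (!is.null(src)) fr <- src[, , f]
    com[f, , 1] <- tapply(fr[lip_rows, 1], fac, mean)
    com[f, , 2] <- tapply(fr[lip_rows, 2], fac, mean)
  }
  if (is.null(src)) {
    com <- unwrap_lateral(com, trajectory$box[1, 1:2])
  }

  if (remove_protein_com) {
    pro <- which(a$kind == "protein")
    pc <- t(vapply(seq_len(nf), function(f) {
      colMeans(trajectory$coords[pro, 1:2, f, drop = FALSE])
    }, numeric(2)))
    drift <- sweep(pc, 2, pc[1, ])
    com[, , 1] <- com[, , 1] - drift[, 1]
    com[, , 2] <- com[, , 2] - drift[, 2]
  }

  msd <- numeric(nf)
  for (li in seq_len(nlip)) {
    msd <- msd + msd_fft(com[, li, 1]) + msd_fft(com[, li, 2])
  }
  msd <- msd / nlip
  out <- data.frame(lag_ns = (seq_len(nf) - 1) * trajectory$dt,
                    msd_A2 = msd,
                    n_pairs = nlip * (nf - seq_len(nf) + 1L))
  structure(out, class = c("sl_msd", "data.frame"),
            dt = trajectory$dt, label = label)
}

# exact all-origin MSD of a 1D signal via FFT autocorrelation
# (Frenkel & Smit order-N algorithm)
msd_fft <- function(x) {
  n <- length(x)
  d <- x^2
  # autocorrelation S2(k) = sum_t x(t) x(t+k) via zero-padded FFT
  m <- 2^ceiling(log2(2 * n))
  fx <- stats::fft(c(x, rep(0, m - n)))
  s2 <- Re(stats::fft(fx * Conj(fx), inverse = TRUE))[1:n] / m
  q <- 2 * sum(d)
  s1 <- numeric(n)
  for (k in seq_len(n)) {
    if (k > 1) q <- q - d[k - 1] - d[n - k + 2]
    s1[k] <- q / (n - k + 1)
  }
  s1 - 2 * s2 / (n - seq_len(n) + 1)
}

#' Fit a lateral diffusion coefficient to an MSD curve
#'
#' Least-squares line (free intercept) through the MSD restricted to a lag
#' window given as fractions of the maximum lag; `D = slope / 4` for
#' two-dimensional diffusion, converted from A^2/ns to nm^2/us.
#'
#' @param msd an [lateral_msd()] curve.
#' @param window length-2 fractions of the maximum lag (default
#'   `c(0.1, 0.5)`).
#' @return list of class `sl_diffusion`: `D_nm2_per_us`, `slope_A2_per_ns`,
#'   `intercept_A2`, `r_squared`, `window_ns`, `n_points`, `label`.
#' @export
fit_diffusion <- function(msd, window = c(0.1, 0.5)) {
  if (length(window) != 2 || window[1] >= window[2]) {
    stopf("window must be two increasing fractions of the maximum lag")
  }
  tmax <- max(msd$lag_ns)
  sel <- msd$lag_ns >= window[1] * tmax & msd$lag_ns <= window[2] * tmax
  if (sum(sel) < 2) stopf("fewer than 2 lags inside the fit window")
  fit <- stats::lm(msd_A2 ~ lag_ns, data = msd[sel, ])
  slope <- unname(stats::coef(fit)[2])
  structure(list(
    D_nm2_per_us = slope / 4 * A2_PER_NS_TO_NM2_PER_US,
    slope_A2_per_ns = slope,
    intercept_A2 = unname(stats::coef(fit)[1]),
    r_squared = suppressWarnings(summary(fit)$r.squared),
    window_ns = range(msd$lag_ns[sel]),
    n_points = sum(sel),
    label = attr(msd, "label")), class = "sl_diffusion")
}

#' @export
print.sl_diffusion <- function(x, ...) {
  cat(sprintf(
    "<sl_diffusion> %s: D = %.3f nm^2/us (slope %.4f A^2/ns, R^2 = %.4f, window %.4g-%.4g ns)\n",
    x$label, x$D_nm2_per_us, x$slope_A2_per_ns, x$r_squared,
    x$window_ns[1], x$window_ns[2]))
  invisible(x)
}

#' Root-mean-square lateral displacement implied by a diffusion coefficient
#'
#' For two-dimensional diffusion, `RMSD(t) = sqrt(4 D t)`.
#'
#' @param D lateral diffusion coefficient, nm^2/us.
#' @param t time, us.
#' @return displacement in nm.
#' @examples
#' rmsd_from_D(1.47, 1.7)  # ~3.16 nm, bulk lipids over 1.7 us
#' rmsd_from_D(0.68, 1.7)  # ~2.15 nm, first-shell lipids
#' @export
rmsd_from_D <- function(D, t) {
  if (any(D < 0) || any(t < 0)) stopf("D and t must be non-negative")
  sqrt(4 * D * t)
}
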