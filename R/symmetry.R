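# Symmetry expansion of per-subunit lipid poses.

#' Expand per-subunit lipid poses by rotational symmetry
#'
#' Given the lipid poses resolved for one subunit of a C-symmetric
#' oligomer, generate the full complement by rotating each pose by
#' k * 360/n_fold degrees (k = 0 .. n_fold - 1) about the pore axis.
#' Five poses per subunit of a pentamer expand to 25 lipid records.
#'
#' @param poses data.frame with at least columns `x`, `y`, `z` (one row
#'   per lipid atom or per lipid, Angstrom); other columns are carried
#'   through.
#' @param center length-2 or -3 (x, y) position of the symmetry axis.
#' @param n_fold symmetry order (default 5).
#' @return data.frame of `n_fold * nrow(poses)` records with added columns
#'   `copy` (1 .. n_fold) and rotated coordinates.
#' @export
c5_expand <- function(poses, center = c(0, 0), n_fold = 5L) {
  if (!all(c("x", "y", "z") %in% names(poses))) {
    stopf("poses need x, y, z columns")
  }
  out <- vector("list", n_fold)
  for (k in seq_len(n_fold)) {
    ang <- 2 * pi * (k - 1) / n_fold
    ca <- cos(ang); sa <- sin(ang)
    p <- poses
    dx <- poses$x - center[1]
    dy <- poses$y - center[2]
    p$x <- center[1] + ca * dx - sa * dy
    p$y <- center[2] + sa * dx + ca * dy
    p$copy <- k
    out[[k]] <- p
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
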