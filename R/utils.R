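# Internal numeric helpers shared across modules.

#' Pairwise minimum-image squared distances
#'
#' Squared Euclidean distances between two coordinate sets under the
#' minimum-image convention for an orthorhombic box.  A box component that
#' is `NA`, `Inf` or non-positive disables wrapping along that axis.
#'
#' @param a,b numeric matrices (n x 3, m x 3), coordinates in Angstrom.
#' @param box length-3 numeric box vector in Angstrom, or `NULL` for no
#'   periodicity.
#' @return n x m matrix of squared distances.
#' @keywords internal
#' @noRd
cross_dist2 <- function(a, b, box = NULL) {
  a <- as_coord_matrix(a)
  b <- as_coord_matrix(b)
  d2 <- matrix(0, nrow(a), nrow(b))
  for (k in 1:3) {
    dk <- outer(a[, k], b[, k], "-")
    if (!is.null(box)) {
      bk <- box[k]
      if (is.finite(bk) && bk > 0) dk <- dk - bk * round(dk / bk)
    }
    d2 <- d2 + dk * dk
  }
  d2
}

as_coord_matrix <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 3, byrow = TRUE)
  if (ncol(x) != 3) stop("coordinates must have 3 columns")
  storage.mode(x) <- "double"
  x
}

#' Wrap coordinates into [0, box) along periodic axes
#' @noRd
wrap_coords <- function(x, box) {
  x <- as_coord_matrix(x)
  for (k in 1:3) {
    bk <- box[k]
    if (is.finite(bk) && bk > 0) x[, k] <- x[, k] - bk * floor(x[, k] / bk)
  }
  x
}

# unit conversion: lateral diffusion coefficients
#   1 nm^2/us = 100 A^2 / 1000 ns = 0.1 A^2/ns
NM2_PER_US_TO_A2_PER_NS <- 0.1
A2_PER_NS_TO_NM2_PER_US <- 10

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Merge short gaps in a logical contact vector
#'
#' Runs of `FALSE` of length <= `gap` that are flanked by `TRUE` runs are
#' flipped to `TRUE`, so that brief losses of contact do not split a run.
#' @noRd
merge_gaps <- function(x, gap) {
  if (gap <= 0L || !any(x)) return(x)
  r <- rle(x)
  n <- length(r$lengths)
  if (n < 3L) return(x)
  inner <- which(!r$values & r$lengths <= gap)
  inner <- inner[inner > 1L & inner < n]
  if (length(inner)) {
    r$values[inner] <- TRUE
    x <- inverse.rle(r)
  }
  x
}

#' Contact run lengths with censoring flags
#'
#' @param x logical vector (contact per frame).
#' @param gap gap tolerance in frames (see [duration_stats()]).
#' @return data.frame with columns `length` (frames) and `censored`
#'   (run touches either trajectory end).
#' @noRd
contact_runs <- function(x, gap = 0L) {
  x <- merge_gaps(x, gap)
  r <- rle(x)
  if (!any(r$values)) {
    return(data.frame(length = integer(), censored = logical()))
  }
  idx <- which(r$values)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(
    length = r$lengths[idx],
    censored = starts[idx] == 1L | ends[idx] == length(x)
  )
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}
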