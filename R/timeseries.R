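#' Construct a masked time-series object
#'
#' Holds one time course per mask voxel together with the voxel geometry.
#'
#' @param data numeric N x T matrix; row i is the time course of mask row i.
#' @param mask a [gm_mask()] with `n` equal to `nrow(data)`.
#' @param normalized logical; `TRUE` if every row already has zero mean and
#'   unit L2 norm.
#' @return An object of class `masked_ts` with fields `data`, `mask`,
#'   `coords_mm`, `coords_vox` and `normalized`.
#' @export
masked_ts <- function(data, mask, normalized = FALSE) {
  stopifnot(inherits(mask, "gm_mask"))
  data <- as.matrix(data)
  if (!is.numeric(data) || any(!is.finite(data)))
    stop("time-series data must be finite numeric")
  if (nrow(data) != mask$n)
    stop("data has ", nrow(data), " rows but the mask has ", mask$n,
         " voxels")
  if (ncol(data) < 2L) stop("need at least 2 timepoints")
  structure(list(data = data, mask = mask, coords_mm = mask$mm,
                 coords_vox = mask$vox, normalized = isTRUE(normalized)),
            class = "masked_ts")
}

#' @export
print.masked_ts <- function(x, ...) {
  cat(sprintf("Masked time series: %d voxels x %d timepoints (%s)\n",
              nrow(x$data), ncol(x$data),
              if (x$normalized) "normalized" else "raw"))
  invisible(x)
}

#' Normalize voxel time courses to zero mean and unit length
#'
#' Each row v is replaced by (v - mean(v)) / ||v - mean(v)||_2.  After this
#' step the Pearson correlation of two voxels equals the dot product of
#' their rows, and corr = 1 - d^2/2 where d is their Euclidean distance,
#' which is what the graph-construction stage relies on.
#'
#' @param ts a [masked_ts()].
#' @return The normalized `masked_ts` (idempotent).
#' @export
normalize_timecourses <- function(ts) {
  stopifnot(inherits(ts, "masked_ts"))
  if (ts$normalized) return(ts)
  d <- ts$data - rowMeans(ts$data)
  nrm <- sqrt(rowSums(d * d))
  bad <- which(nrm <= .Machine$double.eps * ncol(d) * 10)
  if (length(bad)) {
    v <- ts$coords_vox[bad[1L], ]
    stop(sprintf(
      "zero-variance time course at mask row %d (voxel index %d,%d,%d)%s",
      bad[1L], v[1], v[2], v[3],
      if (length(bad) > 1L) sprintf(" and %d more", length(bad) - 1L) else ""))
  }
  ts$data <- d / nrm
  ts$normalized <- TRUE
  ts
}

#' Pearson correlation of two voxels from normalized time courses
#'
#' For unit-norm, zero-mean rows the correlation is the plain dot product;
#' the result is clipped to \[-1, 1\] against floating-point rounding.
#'
#' @param ts_norm a normalized [masked_ts()].
#' @param i,j mask row indices.
#' @return Correlation in \[-1, 1\].
#' @export
ts_correlation <- function(ts_norm, i, j) {
  stopifnot(inherits(ts_norm, "masked_ts"))
  if (!ts_norm$normalized)
    stop("time courses must be normalized first (see normalize_timecourses)")
  r <- sum(ts_norm$data[i, ] * ts_norm$data[j, ])
  min(1, max(-1, r))
}
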