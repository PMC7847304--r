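# Signal-cleaning steps applied after spatial registration, in the fixed
# order: initial-volume discard -> confound regression -> band-pass -> box
# smoothing. All steps are linear operators.

#' Discard initial volumes of a functional series
#'
#' Scanner signal is unstable over the first few volumes; they are dropped
#' before any further processing (five volumes at TR = 2 s by default usage,
#' leaving 300 of 305 acquired).
#'
#' @param series time x ROI (or time x voxel) matrix.
#' @param k Number of initial rows to discard; must leave at least one row.
#' @return The matrix without its first `k` rows.
#' @export
drop_initial_volumes <- function(series, k) {
  stopifnot(is.matrix(series), k >= 0)
  if (k >= nrow(series)) stop("k must be smaller than the number of volumes")
  if (k == 0) return(series)
  series[-seq_len(k), , drop = FALSE]
}

#' Nuisance eigenvector time series from a non-gray-matter compartment
#'
#' Returns the top-k left singular vectors of the column-centered
#' time x voxel matrix: orthonormal time series ordered by explained
#' variance, suitable as physiological nuisance regressors.
#'
#' @param nongray_series time x voxel matrix of non-gray-matter signals.
#' @param k Number of eigenvectors (default 5).
#' @return time x k matrix with orthonormal columns.
#' @export
extract_nuisance_eigenvectors <- function(nongray_series, k = 5) {
  stopifnot(is.matrix(nongray_series))
  if (k > min(dim(nongray_series)))
    stop("k exceeds the rank bound min(rows, columns)")
  x <- scale(nongray_series, center = TRUE, scale = FALSE)
  sv <- svd(x, nu = k, nv = 0)
  if (sv$d[1] < 1e-12 * max(1, nrow(x)))
    stop("input has rank 0 after centering (all columns constant)")
  if (sum(sv$d > 1e-12 * sv$d[1]) < k)
    warning("requested more eigenvectors than the numerical rank")
  sv$u[, seq_len(k), drop = FALSE]
}

#' Regress confounds out of a functional series
#'
#' Ordinary least squares per column against the nuisance design (eigenvector
#' time series and motion parameters), always including an intercept so the
#' residuals are demeaned. Residuals are exactly orthogonal to every
#' regressor.
#'
#' @param series time x ROI matrix.
#' @param nuisance time x q matrix (or data.frame) of confound regressors;
#'   row count must match `series`.
#' @return Residual matrix of the same shape as `series`.
#' @export
regress_confounds <- function(series, nuisance) {
  stopifnot(is.matrix(series))
  nuisance <- as.matrix(nuisance)
  if (nrow(nuisance) != nrow(series))
    stop("nuisance rows must match series rows")
  X <- cbind(`(intercept)` = 1, nuisance)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient confound design; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  series - X %*% qr.coef(qrX, series)
}

#' Zero-phase band-pass filter
#'
#' Forward-backward (zero-phase) Butterworth band-pass of order 5, retaining
#' fluctuations between `low` and `high` Hz. The forward-backward pass
#' squares the magnitude response, so there is no temporal shift; the DC
#' component is removed.
#'
#' @param series time x ROI matrix (filtered per column).
#' @param tr Repetition time in seconds (sampling interval).
#' @param low,high Passband edges in Hz; `0 <= low < high < 1/(2*tr)`.
#' @param order Butterworth order (default 5).
#' @return Filtered matrix, same shape.
#' @export
bandpass <- function(series, tr, low = 0.01, high = 0.1, order = 5) {
  stopifnot(is.matrix(series), tr > 0)
  nyq <- 1 / (2 * tr)
  if (!(low >= 0 && low < high)) stop("need 0 <= low < high")
  if (high >= nyq) stop("high must be below the Nyquist frequency ", nyq, " Hz")
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  # demean first: the passband excludes DC anyway, and removing the mean
  # keeps the forward-backward pass free of large boundary transients
  apply(series, 2, function(y) signal::filtfilt(bf, y - mean(y)))
}

#' Box (moving-average) spatial smoothing
#'
#' Replaces each voxel by the mean over its `kernel_voxels`^3 neighborhood
#' (per volume for 4D input). At the array boundary the window shrinks to
#' the in-bounds voxels, so constant volumes are preserved exactly.
#'
#' @param volume 3D array, or 4D array smoothed volume-by-volume.
#' @param kernel_voxels Odd kernel width (default 3).
#' @return Smoothed array, same shape.
#' @export
box_smooth <- function(volume, kernel_voxels = 3) {
  if (kernel_voxels %% 2 != 1 || kernel_voxels < 1)
    stop("kernel size must be odd and >= 1")
  nd <- length(dim(volume))
  if (!nd %in% c(3L, 4L)) stop("volume must be a 3D or 4D array")
  if (nd == 4L) {
    out <- volume
    for (t in seq_len(dim(volume)[4]))
      out[, , , t] <- box_smooth(volume[, , , t], kernel_voxels)
    return(out)
  }
  if (kernel_voxels == 1) return(volume)
  h <- (kernel_voxels - 1) / 2
  acc <- array(0, dim(volume))
  cnt <- array(0, dim(volume))
  dims <- dim(volume)
  for (dx in -h:h) for (dy in -h:h) for (dz in -h:h) {
    sx <- shift_range(dims[1], dx); sy <- shift_range(dims[2], dy)
    sz <- shift_range(dims[3], dz)
    acc[sx$to, sy$to, sz$to] <- acc[sx$to, sy$to, sz$to] +
      volume[sx$from, sy$from, sz$from]
    cnt[sx$to, sy$to, sz$to] <- cnt[sx$to, sy$to, sz$to] + 1
  }
  acc / cnt
}

# index ranges for a shifted copy: destination voxel v receives source v + d
shift_range <- function(n, d) {
  if (d >= 0) list(to = seq_len(n - d), from = seq_len(n - d) + d)
  else list(to = seq(1 - d, n), from = seq_len(n + d))
}

#' Full preprocessing chain for one ROI/voxel time-series matrix
#'
#' Applies, in order: initial-volume discard, confound regression (when a
#' nuisance design is supplied), and zero-phase band-pass filtering. Spatial
#' smoothing applies to volumes, not ROI matrices; see [box_smooth].
#'
#' @param series time x ROI matrix.
#' @param tr Repetition time (s).
#' @param drop_volumes Initial volumes to discard (default 5).
#' @param nuisance Optional confound matrix aligned to the series *after*
#'   volume discard.
#' @param band Passband in Hz (default `c(0.01, 0.1)`).
#' @return Cleaned time x ROI matrix.
#' @export
preprocess_series <- function(series, tr, drop_volumes = 5, nuisance = NULL,
                              band = c(0.01, 0.1)) {
  out <- drop_initial_volumes(series, drop_volumes)
  if (!is.null(nuisance)) out <- regress_confounds(out, nuisance)
  bandpass(out, tr = tr, low = band[1], high = band[2])
}
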