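# Dual regression: back-projection of group-level spatial maps onto a
# subject's 4D data (stage 1: per-time-point multivariate OLS giving subject
# time series; stage 2: per-voxel OLS giving subject maps), plus a paired
# sign-flip permutation test for session differences with max-statistic FWE
# control. Group maps are inputs: ICA estimation is out of scope.

#' Dual regression, stage 1: subject-specific time series
#'
#' At each time point, the subject's volume is regressed on the k group maps
#' (multivariate OLS, no intercept); the coefficient trajectories are the
#' subject's time series, one per map.
#'
#' @param group_maps voxel x k matrix of group-level spatial maps (linearly
#'   independent columns).
#' @param subject_4d time x voxel matrix.
#' @return time x k matrix of subject time series.
#' @export
dual_regression_stage1 <- function(group_maps, subject_4d) {
  M <- as.matrix(group_maps)
  Y <- as.matrix(subject_4d)
  if (ncol(Y) != nrow(M)) stop("voxel grids of maps and data do not match")
  q <- qr(M)
  if (q$rank < ncol(M)) stop("group maps are collinear")
  t(qr.coef(q, t(Y)))
}

#' Dual regression, stage 2: subject-specific spatial maps
#'
#' Each voxel's time course is regressed on the subject's k time series; the
#' coefficients form the subject's spatial maps.
#'
#' @param subject_4d time x voxel matrix.
#' @param subject_series time x k matrix (full column rank).
#' @return k x voxel matrix of subject maps.
#' @export
dual_regression_stage2 <- function(subject_4d, subject_series) {
  S <- as.matrix(subject_series)
  Y <- as.matrix(subject_4d)
  if (nrow(Y) != nrow(S)) stop("time dimensions do not match")
  q <- qr(S)
  if (q$rank < ncol(S)) stop("subject time series are rank deficient")
  qr.coef(q, Y)
}

#' Paired sign-flip permutation test on matched subject maps
#'
#' Voxel-wise paired t-test between two sessions' subject maps; the null
#' distribution of the maximum absolute t over voxels is built by randomly
#' flipping the sign of each subject's difference map, giving
#' family-wise-error corrected voxel p-values
#' `(1 + #{null max >= |t|}) / (1 + n_perm)`.
#'
#' @param maps_A,maps_B subjects x voxel matrices, same subjects in the same
#'   order (rownames, when present, must agree).
#' @param n_perm Number of sign-flip permutations.
#' @param seed Integer seed.
#' @return List with `t` (voxel vector), `p_fwe`, `null_max`, `df`.
#' @export
paired_signflip_test <- function(maps_A, maps_B, n_perm = 5000, seed = NULL) {
  A <- as.matrix(maps_A); B <- as.matrix(maps_B)
  if (!all(dim(A) == dim(B))) stop("unmatched map dimensions")
  if (!is.null(rownames(A)) && !is.null(rownames(B)) &&
      !identical(rownames(A), rownames(B)))
    stop("unmatched subjects between sessions")
  n <- nrow(A)
  if (n < 6) stop("need at least 6 matched pairs")
  if (!is.null(seed)) set.seed(seed)
  D <- A - B
  tstat <- function(M) {
    m <- colMeans(M)
    se <- sqrt(apply(M, 2, var) / nrow(M))
    ifelse(se == 0, 0, m / se)
  }
  t_obs <- tstat(D)
  signs <- matrix(sample(c(-1, 1), n * n_perm, replace = TRUE), n_perm, n)
  null_max <- vapply(seq_len(n_perm), function(b)
    max(abs(tstat(D * signs[b, ]))), numeric(1))
  p_fwe <- vapply(abs(t_obs), function(tv)
    (1 + sum(null_max >= tv)) / (1 + n_perm), numeric(1))
  list(t = t_obs, p_fwe = p_fwe, null_max = null_max, df = n - 1)
}
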