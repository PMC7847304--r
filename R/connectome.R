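#' Canonical edge indexing for symmetric connectivity matrices
#'
#' Edges are the upper-triangle entries (i < j) of an ROI x ROI matrix,
#' enumerated in row-major order: (1,2), (1,3), ..., (1,p), (2,3), ...
#' The map is a bijection between edge id and ROI pair, shared by every
#' function in the package, so edge ids are stable across runs.
#'
#' @param rois Character vector of ROI labels (unique), or a single integer
#'   giving the number of ROIs.
#' @return A data.frame with columns `edge` (integer id), `i`, `j` (1-based
#'   ROI indices, i < j), `roi_i`, `roi_j`, `label` ("A--B").
#' @examples
#' nrow(edge_index_map(roi_set()))   # 16 ROIs -> 120 edges
#' nrow(edge_index_map(9))           # 36
#' @export
edge_index_map <- function(rois) {
  if (is.numeric(rois) && length(rois) == 1L) rois <- paste0("R", seq_len(rois))
  if (anyDuplicated(rois)) stop("ROI labels must be unique")
  p <- length(rois)
  ij <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  ij <- ij[order(ij[, "row"], ij[, "col"]), , drop = FALSE]  # row-major
  data.frame(
    edge = seq_len(nrow(ij)),
    i = unname(ij[, "row"]), j = unname(ij[, "col"]),
    roi_i = rois[ij[, "row"]], roi_j = rois[ij[, "col"]],
    label = paste0(rois[ij[, "row"]], "--", rois[ij[, "col"]]),
    stringsAsFactors = FALSE
  )
}

#' Vectorize a symmetric matrix into its canonical edge vector
#'
#' @param m Symmetric numeric matrix (asymmetry beyond `tol` is an error).
#' @param tol Symmetry tolerance.
#' @return Named numeric vector of upper-triangle values in canonical
#'   (row-major) order, with the edge map in attribute `"edge_map"`.
#' @seealso [devectorize_edges] for the exact inverse.
#' @export
vectorize_edges <- function(m, tol = 1e-10) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (max(abs(m - t(m)), na.rm = TRUE) > tol)
    stop("matrix is not symmetric within tolerance ", tol)
  rois <- rownames(m)
  if (is.null(rois)) rois <- paste0("R", seq_len(nrow(m)))
  map <- edge_index_map(rois)
  v <- m[cbind(map$i, map$j)]
  names(v) <- map$label
  attr(v, "edge_map") <- map
  v
}

#' @param v Edge vector as produced by [vectorize_edges].
#' @param diag Value placed on the diagonal (default `NA`).
#' @rdname vectorize_edges
#' @export
devectorize_edges <- function(v, diag = NA_real_) {
  map <- attr(v, "edge_map")
  if (is.null(map)) stop("edge vector lacks an edge_map attribute")
  p <- max(map$j)
  m <- matrix(diag, p, p)
  m[cbind(map$i, map$j)] <- v
  m[cbind(map$j, map$i)] <- v
  rois <- character(p); rois[map$i] <- map$roi_i; rois[map$j] <- map$roi_j
  dimnames(m) <- list(rois, rois)
  m
}

#' ROI-mean time series from a 4D volume series
#'
#' Averages voxel time courses within each labelled ROI mask.
#'
#' @param volume_series 4D numeric array (x, y, z, time).
#' @param roi_masks Integer/numeric 3D array of voxel labels (0 = background),
#'   or a list of logical 3D masks named by ROI.
#' @param rois Character vector naming and ordering the ROIs. For a labelled
#'   array, label `k` corresponds to `rois[k]`.
#' @return time x ROI matrix with ROI labels as column names.
#' @export
roi_mean_timeseries <- function(volume_series, roi_masks, rois = NULL) {
  stopifnot(length(dim(volume_series)) == 4L)
  nt <- dim(volume_series)[4]
  vox <- matrix(volume_series, ncol = nt)  # voxel x time
  if (is.list(roi_masks)) {
    if (is.null(rois)) rois <- names(roi_masks)
    idx <- lapply(roi_masks, function(m) which(as.logical(m)))
  } else {
    labs <- as.integer(round(roi_masks))
    if (is.null(rois)) rois <- paste0("R", sort(unique(labs[labs > 0])))
    idx <- lapply(seq_along(rois), function(k) which(labs == k))
  }
  names(idx) <- rois
  if (length(Reduce(intersect, idx)) > 0 && length(idx) > 1)
    stop("ROI masks overlap")
  out <- matrix(NA_real_, nt, length(rois), dimnames = list(NULL, rois))
  for (k in seq_along(idx)) {
    if (length(idx[[k]]) == 0L) stop("empty mask for ROI ", rois[k])
    out[, k] <- colMeans(vox[idx[[k]], , drop = FALSE])
  }
  out
}

#' Partial-correlation matrix of ROI time series
#'
#' Entry (i, j) is the correlation between ROI i and ROI j after regressing
#' out all remaining ROI time series, computed through the inverse covariance
#' (precision) matrix: `p_ij = -omega_ij / sqrt(omega_ii * omega_jj)`.
#' An optional ridge term stabilises near-singular covariance (default off;
#' with ~300 time points and 16 ROIs the sample estimator is well posed).
#'
#' @param series time x ROI numeric matrix; more rows than `ncol + 2`.
#' @param ridge Non-negative ridge added to the covariance diagonal as
#'   `ridge * mean(diag(cov))`.
#' @return Symmetric ROI x ROI matrix with unit diagonal.
#' @export
partial_correlation_matrix <- function(series, ridge = 0) {
  stopifnot(is.matrix(series))
  p <- ncol(series)
  if (nrow(series) <= p + 2) stop("need more time points than ROIs + 2")
  sds <- apply(series, 2, sd)
  if (any(sds == 0)) {
    bad <- colnames(series)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop("constant column(s): ", paste(bad, collapse = ", "))
  }
  S <- cov(series)
  if (ridge > 0) S <- S + diag(ridge * mean(diag(S)), p)
  omega <- tryCatch(solve(S), error = function(e)
    stop("singular covariance matrix; consider ridge > 0"))
  d <- 1 / sqrt(diag(omega))
  pc <- -omega * tcrossprod(d)
  diag(pc) <- 1
  pc <- (pc + t(pc)) / 2
  dimnames(pc) <- list(colnames(series), colnames(series))
  pc
}

#' Fisher z-transform of a correlation
#'
#' `z = atanh(r)`, variance-stabilising before linear modelling.
#'
#' @param r Correlation value(s), strictly inside (-1, 1).
#' @return z-value(s) of the same shape.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1, na.rm = TRUE)) stop("|r| must be < 1")
  atanh(r)
}

#' Stack of Fisher-z partial-correlation connectomes
#'
#' Builds the canonical per-dataset edge representation from an ROI
#' time-series panel: one Fisher z-transformed partial-correlation matrix per
#' (subject, session), stored as a dataset x edge matrix together with the
#' shared edge index map.
#'
#' @param panel An `roi_panel` (see [generate_cohort]) or a list of time x ROI
#'   matrices; when a plain list, `subject`, `session` and `sex` vectors of
#'   matching length must be given.
#' @param subject,session,sex Metadata per list element (ignored for an
#'   `roi_panel`).
#' @param ridge Passed to [partial_correlation_matrix].
#' @return An object of class `connectome_stack`: list with `z` (dataset x
#'   edge matrix of Fisher-z partial correlations), `subject`, `session`,
#'   `sex`, `rois`, `edge_map`.
#' @export
connectome_stack <- function(panel, subject = NULL, session = NULL,
                             sex = NULL, ridge = 0) {
  if (inherits(panel, "roi_panel")) {
    series <- panel$series
    subject <- panel$meta$subject
    session <- panel$meta$session
    sex <- panel$meta$sex
  } else {
    series <- panel
    if (is.null(subject) || is.null(session))
      stop("subject and session metadata required for a plain list")
    if (is.null(sex)) sex <- rep(NA_character_, length(series))
  }
  stopifnot(length(series) >= 1)
  rois <- colnames(series[[1]])
  if (is.null(rois)) rois <- paste0("R", seq_len(ncol(series[[1]])))
  map <- edge_index_map(rois)
  z <- t(vapply(series, function(s) {
    pc <- partial_correlation_matrix(s, ridge = ridge)
    fisher_z(pc[cbind(map$i, map$j)])
  }, numeric(nrow(map))))
  colnames(z) <- map$label
  structure(list(z = z, subject = as.character(subject),
                 session = as.integer(session), sex = as.character(sex),
                 rois = rois, edge_map = map),
            class = "connectome_stack")
}

#' @export
print.connectome_stack <- function(x, ...) {
  cat("Connectome stack: ", nrow(x$z), " datasets, ", length(x$rois),
      " ROIs, ", ncol(x$z), " edges\n", sep = "")
  cat("Sessions: ", paste(sort(unique(x$session)), collapse = ", "),
      "; subjects: ", length(unique(x$subject)), "\n", sep = "")
  invisible(x)
}

#' Extract one session's edge matrix from a stack
#'
#' @param stack A `connectome_stack`.
#' @param session Session label to select.
#' @return subjects x edges matrix with subject ids as row names.
#' @export
session_edges <- function(stack, session) {
  stopifnot(inherits(stack, "connectome_stack"))
  sel <- stack$session == session
  if (!any(sel)) stop("no datasets for session ", session)
  m <- stack$z[sel, , drop = FALSE]
  rownames(m) <- stack$subject[sel]
  m
}
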