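# Plain-text serialization: TSV for matrices and time series, CSV for
# behavior tables, JSON for manifests and results. Floats are written with
# 17 significant digits so numeric round-trips are exact at double
# precision. Optional NIfTI support goes through RNifti when installed.

fmt_num <- function(x) formatC(x, digits = 17, format = "g")

write_matrix_tsv <- function(m, path) {
  df <- as.data.frame(apply(m, 2, fmt_num), stringsAsFactors = FALSE)
  colnames(df) <- colnames(m)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  as.matrix(vapply(df, as.numeric, numeric(nrow(df))))
}

#' Write / read a synthetic cohort as plain text
#'
#' One TSV per retained (subject, session) time series, a JSON manifest
#' (design, metadata, file list) and a behavior CSV. The round-trip
#' preserves numeric values exactly and missingness markers in the behavior
#' table.
#'
#' @param cohort A `synthetic_cohort` (or any list with `panel` and
#'   `behavior`).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly; `read_cohort` returns a list with `panel`,
#'   `behavior`, `manifest`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- cohort$panel$meta
  files <- sprintf("timeseries_%s_ses%d.tsv", meta$subject, meta$session)
  for (k in seq_along(cohort$panel$series))
    write_matrix_tsv(cohort$panel$series[[k]], file.path(dir, files[k]))
  beh <- cohort$behavior
  num <- vapply(beh, is.numeric, logical(1))
  beh[num] <- lapply(beh[num], function(v) ifelse(is.na(v), NA, fmt_num(v)))
  utils::write.csv(beh, file.path(dir, "behavior.csv"), row.names = FALSE,
                   quote = FALSE, na = "NA")
  manifest <- list(
    n_datasets = length(files),
    tr = meta$tr[1],
    rois = colnames(cohort$panel$series[[1]]),
    datasets = data.frame(subject = meta$subject, session = meta$session,
                          sex = meta$sex, file = files,
                          stringsAsFactors = FALSE))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  ds <- manifest$datasets
  series <- lapply(ds$file, function(f) read_matrix_tsv(file.path(dir, f)))
  panel <- structure(list(
    series = series,
    meta = data.frame(subject = ds$subject, session = as.integer(ds$session),
                      sex = ds$sex, tr = manifest$tr,
                      stringsAsFactors = FALSE)),
    class = "roi_panel")
  behavior <- utils::read.csv(file.path(dir, "behavior.csv"),
                              stringsAsFactors = FALSE)
  list(panel = panel, behavior = behavior, manifest = manifest)
}

#' Write / read a connectome stack as a directory of TSV matrices
#'
#' Each dataset's ROI x ROI Fisher-z matrix is written as a TSV with ROI
#' label headers, keyed by subject/session in a JSON manifest. Values
#' round-trip exactly.
#'
#' @param stack A [connectome_stack].
#' @param dir Target directory.
#' @return `dir` invisibly; `read_stack` returns the reconstructed
#'   `connectome_stack`.
#' @export
write_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "connectome_stack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("connectome_%s_ses%d.tsv", stack$subject, stack$session)
  for (k in seq_len(nrow(stack$z))) {
    v <- stack$z[k, ]
    attr(v, "edge_map") <- stack$edge_map
    write_matrix_tsv(devectorize_edges(v, diag = 0), file.path(dir, files[k]))
  }
  manifest <- list(
    rois = stack$rois, edge_order = "upper-triangle row-major, v1",
    datasets = data.frame(subject = stack$subject, session = stack$session,
                          sex = stack$sex, file = files,
                          stringsAsFactors = FALSE))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_stack
#' @export
read_stack <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  ds <- manifest$datasets
  rois <- manifest$rois
  map <- edge_index_map(rois)
  z <- t(vapply(ds$file, function(f) {
    m <- read_matrix_tsv(file.path(dir, f))
    m[cbind(map$i, map$j)]
  }, numeric(nrow(map))))
  rownames(z) <- NULL
  colnames(z) <- map$label
  structure(list(z = z, subject = ds$subject,
                 session = as.integer(ds$session), sex = ds$sex,
                 rois = rois, edge_map = map),
            class = "connectome_stack")
}

#' Serialize network-based-statistic results to JSON
#'
#' Components (node names, edge lists, strengths, FWE p-values), per-edge
#' statistics and the null-distribution summary survive a round-trip
#' unchanged.
#'
#' @param x An [nbs_glm] or [nbr_lmm] object.
#' @param path JSON file path.
#' @return `path` invisibly; `read_nbs_result` returns the restored object.
#' @export
write_nbs_result <- function(x, path) {
  stopifnot(inherits(x, c("nbs_glm", "nbr_lmm")))
  payload <- unclass(x)
  payload$call <- paste(deparse(payload$call), collapse = " ")
  payload$data <- NULL            # long tables are stored with the cohort
  if (!is.null(payload$fixed)) payload$fixed <- deparse(payload$fixed)
  payload$class <- class(x)[1]
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_nbs_result
#' @export
read_nbs_result <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  cls <- raw$class
  df_from_rows <- function(rows) {
    out <- do.call(rbind, lapply(rows, function(r)
      as.data.frame(lapply(r, function(v) if (is.null(v)) NA else v),
                    stringsAsFactors = FALSE)))
    rownames(out) <- NULL
    out
  }
  comp_from <- function(cc) {
    ed <- df_from_rows(cc$edges)
    ed$edge <- as.integer(ed$edge); ed$stat <- as.numeric(ed$stat)
    list(nodes = unlist(cc$nodes), edges = ed,
         strength = as.numeric(cc$strength),
         n_edges = as.integer(cc$n_edges), p_fwe = as.numeric(cc$p_fwe))
  }
  null_from <- function(nm, nms) {  # serialized row-wise
    m <- do.call(rbind, lapply(nm, function(row) as.numeric(unlist(row))))
    if (is.null(dim(m))) m <- matrix(m, ncol = length(nms))
    colnames(m) <- nms
    m
  }
  if (cls == "nbs_glm") {
    obj <- list(
      stats = vapply(raw$stats, as.numeric, numeric(1)), df = raw$df,
      components = lapply(raw$components, function(d) lapply(d, comp_from)),
      null_max = null_from(raw$null_max, names(raw$components)),
      t_thresh = raw$t_thresh, n_perm = raw$n_perm, seed = raw$seed,
      direction = raw$direction, edge_map = df_from_rows(raw$edge_map),
      n_subjects = raw$n_subjects, call = raw$call)
  } else {
    obj <- list(
      results = lapply(raw$results, function(rr) {
        st <- df_from_rows(rr$stats)
        for (cl in intersect(c("F", "p", "z"), names(st)))
          st[[cl]] <- as.numeric(st[[cl]])
        st$edge <- as.integer(st$edge)
        list(stats = st,
             components = lapply(rr$components, comp_from),
             excluded = as.integer(unlist(rr$excluded)))
      }),
      null_max = null_from(raw$null_max, names(raw$results)),
      alpha_edge = raw$alpha_edge, n_perm = raw$n_perm, seed = raw$seed,
      fixed = stats::as.formula(raw$fixed),
      terms = unlist(raw$terms), edge_map = df_from_rows(raw$edge_map),
      n_obs = raw$n_obs, n_subjects = raw$n_subjects, call = raw$call)
  }
  structure(obj, class = cls)
}

#' Read / write 4D volumes as NIfTI (optional)
#'
#' Thin wrappers over RNifti for users whose data live in NIfTI files;
#' RNifti is a suggested dependency.
#'
#' @param path NIfTI file.
#' @param data Numeric array to write.
#' @return `read_nifti_volume` returns a plain numeric array.
#' @export
read_nifti_volume <- function(path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("RNifti is required for NIfTI input")
  a <- RNifti::readNifti(path)
  array(as.numeric(a), dim = dim(a))
}

#' @rdname read_nifti_volume
#' @export
write_nifti_volume <- function(data, path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("RNifti is required for NIfTI output")
  RNifti::writeNifti(RNifti::asNifti(data), path)
  invisible(path)
}
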