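# Cross-sectional network-based statistic: edge-wise linear model against a
# behavioral covariate, fixed statistic threshold, connected components, and
# permutation FWE control on component strength.

#' Edge-wise T statistics for a behavioral covariate
#'
#' Per edge, ordinary least squares of the edge value on the covariate
#' (intercept always included, plus optional nuisance covariates); the
#' returned statistic is the covariate's slope estimate divided by its
#' standard error.
#'
#' @param edge_values subjects x edges numeric matrix.
#' @param covariate Numeric vector, one value per subject; no missing values.
#' @param nuisance Optional matrix of nuisance covariates (subjects x q).
#' @return Numeric vector of T statistics (one per edge) with the residual
#'   degrees of freedom in attribute `"df"`.
#' @export
edge_glm_stats <- function(edge_values, covariate, nuisance = NULL) {
  stopifnot(is.matrix(edge_values), length(covariate) == nrow(edge_values))
  if (anyNA(covariate)) stop("covariate contains missing values")
  if (sd(covariate) == 0) stop("constant covariate: zero design variance")
  X <- cbind(1, nuisance, covariate)
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("need n_subjects > n_regressors + 1")
  qrX <- qr(X)
  if (qrX$rank < p) stop("rank-deficient design")
  coefs <- qr.coef(qrX, edge_values)
  res <- edge_values - X %*% coefs
  df <- n - p
  s2 <- colSums(res^2) / df
  cii <- solve(crossprod(X))[p, p]
  tt <- coefs[p, ] / sqrt(s2 * cii)
  attr(tt, "df") <- df
  tt
}

#' Suprathreshold connected components of an edge-statistic vector
#'
#' Edges with statistic beyond the fixed threshold (in the requested
#' direction) form a graph on the ROIs; its maximal connected components are
#' returned, each with its node set, edge table and strength (sum of absolute
#' edge statistics, the "intensity" definition).
#'
#' @param stats Per-edge statistics in canonical edge order.
#' @param edge_map Edge index map ([edge_index_map]).
#' @param t_thresh Positive fixed threshold.
#' @param direction `"positive"` keeps `stat > t_thresh`, `"negative"` keeps
#'   `stat < -t_thresh`.
#' @return List of components, each a list with `nodes`, `edges` (data.frame
#'   with `edge`, `label`, `stat`), `strength`, `n_edges`; ordered by
#'   decreasing strength. Empty list when no edge passes.
#' @export
threshold_and_components <- function(stats, edge_map, t_thresh,
                                     direction = c("positive", "negative")) {
  direction <- match.arg(direction)
  stopifnot(t_thresh > 0, length(stats) == nrow(edge_map))
  keep <- if (direction == "positive") stats > t_thresh else stats < -t_thresh
  keep[is.na(keep)] <- FALSE
  build_components(stats, edge_map, keep)
}

# shared component assembly from a logical keep vector
build_components <- function(stats, edge_map, keep) {
  if (!any(keep)) return(list())
  n_nodes <- max(edge_map$j)
  sub <- edge_map[keep, , drop = FALSE]
  lab <- cpp_edge_components(sub$i, sub$j, n_nodes)
  comps <- lapply(unique(lab), function(l) {
    rows <- sub[lab == l, , drop = FALSE]
    st <- stats[rows$edge]
    list(nodes = sort(unique(c(rows$roi_i, rows$roi_j))),
         edges = data.frame(edge = rows$edge, label = rows$label,
                            stat = unname(st), stringsAsFactors = FALSE),
         strength = sum(abs(st)),
         n_edges = nrow(rows))
  })
  comps[order(vapply(comps, `[[`, numeric(1), "strength"), decreasing = TRUE)]
}

#' Strength ("intensity") of a network component
#'
#' Sum of absolute edge statistics over the component's edges.
#'
#' @param component A component as returned by [threshold_and_components].
#' @param stats Optional per-edge statistic vector; when omitted the
#'   statistics stored in the component are used.
#' @return Numeric strength.
#' @export
component_strength <- function(component, stats = NULL) {
  if (is.null(stats)) return(sum(abs(component$edges$stat)))
  sum(abs(stats[component$edges$edge]))
}

#' Network-based statistic for edge-behavior association (GLM + permutation FWE)
#'
#' Fits the edge-wise linear model, forms suprathreshold components at the
#' fixed threshold `t_thresh`, and assigns each component a family-wise error
#' corrected p-value by comparing its strength with the null distribution of
#' the maximum component strength under permutation of the covariate across
#' subjects (5000 permutations by default). With nuisance covariates the
#' Freedman-Lane scheme is used (nuisance-model residuals are permuted).
#' FWE p-values use the add-one estimator `(1 + #{null >= obs}) / (1 + B)`,
#' so no p-value is ever zero.
#'
#' @param edge_values subjects x edges matrix (e.g. [session_edges] of a
#'   [connectome_stack]), or a `connectome_stack` (then `covariate` is a
#'   column name of `behavior` and `session` selects the datasets).
#' @param covariate Per-subject behavioral value (or column name).
#' @param nuisance Optional nuisance covariate matrix.
#' @param t_thresh Fixed edge threshold on T (default 1.7).
#' @param n_perm Number of permutations (>= 100; default 5000).
#' @param seed Integer seed for the permutation stream.
#' @param direction `"both"` (default) tests the positive and negative
#'   contrasts separately, each against its own null.
#' @param behavior,session Used only for the `connectome_stack` interface.
#' @return Object of class `nbs_glm`: per-edge stats, components per
#'   direction with FWE p-values, the null distributions, and the settings.
#' @examples
#' set.seed(1)
#' y <- matrix(rnorm(20 * 15), 20, 15)
#' fit <- nbs_glm(y, rnorm(20), edge_map = edge_index_map(6),
#'                n_perm = 199, seed = 7)
#' print(fit)
#' @export
nbs_glm <- function(edge_values, covariate, nuisance = NULL, t_thresh = 1.7,
                    n_perm = 5000, seed = NULL,
                    direction = c("both", "positive", "negative"),
                    behavior = NULL, session = 1, edge_map = NULL) {
  direction <- match.arg(direction)
  if (inherits(edge_values, "connectome_stack")) {
    stack <- edge_values
    edge_map <- stack$edge_map
    edge_values <- session_edges(stack, session)
    if (is.character(covariate)) {
      stopifnot(!is.null(behavior), covariate %in% names(behavior))
      covariate <- behavior[[covariate]][match(rownames(edge_values),
                                               behavior$subject)]
    }
    keep <- !is.na(covariate)
    edge_values <- edge_values[keep, , drop = FALSE]
    covariate <- covariate[keep]
  }
  if (is.null(edge_map)) {
    p <- (1 + sqrt(1 + 8 * ncol(edge_values))) / 2
    if (p != round(p)) stop("edge count is not p*(p-1)/2; supply edge_map")
    edge_map <- edge_index_map(as.integer(p))
  }
  if (n_perm < 100) stop("n_perm must be at least 100")
  if (!is.null(seed)) set.seed(seed)

  obs <- edge_glm_stats(edge_values, covariate, nuisance)
  dirs <- if (direction == "both") c("positive", "negative") else direction
  comps <- lapply(dirs, function(d)
    threshold_and_components(obs, edge_map, t_thresh, d))
  names(comps) <- dirs

  n <- nrow(edge_values)
  n_nodes <- max(edge_map$j)
  if (!is.null(nuisance)) {  # Freedman-Lane: permute reduced-model residuals
    Z <- cbind(1, nuisance)
    fitted0 <- Z %*% qr.coef(qr(Z), edge_values)
    res0 <- edge_values - fitted0
  }
  null_max <- matrix(0, n_perm, length(dirs), dimnames = list(NULL, dirs))
  for (b in seq_len(n_perm)) {
    idx <- sample.int(n)
    st <- if (is.null(nuisance))
      edge_glm_stats(edge_values, covariate[idx], NULL)
    else
      edge_glm_stats(fitted0 + res0[idx, , drop = FALSE], covariate, nuisance)
    for (d in dirs) {
      keep <- if (d == "positive") st > t_thresh else st < -t_thresh
      keep[is.na(keep)] <- FALSE
      null_max[b, d] <- cpp_max_component_strength(
        ifelse(keep, st, 0), edge_map$i, edge_map$j, n_nodes, keep)
    }
  }
  for (d in dirs) {
    for (k in seq_along(comps[[d]])) {
      s <- comps[[d]][[k]]$strength
      comps[[d]][[k]]$p_fwe <- (1 + sum(null_max[, d] >= s)) / (1 + n_perm)
    }
  }
  structure(list(stats = obs, df = attr(obs, "df"), components = comps,
                 null_max = null_max, t_thresh = t_thresh, n_perm = n_perm,
                 seed = seed, direction = direction, edge_map = edge_map,
                 n_subjects = n, call = match.call()),
            class = "nbs_glm")
}

#' @export
print.nbs_glm <- function(x, ...) {
  cat("Network-based statistic (edge-wise GLM)\n")
  cat("  ", length(x$stats), " edges, ", x$n_subjects, " subjects, T > ",
      x$t_thresh, ", ", x$n_perm, " permutations\n", sep = "")
  for (d in names(x$components)) {
    cs <- x$components[[d]]
    if (!length(cs)) { cat("  ", d, ": no suprathreshold component\n", sep = ""); next }
    for (k in seq_along(cs))
      cat(sprintf("  %s component %d: %d edges, %d nodes, strength %.2f, FWE p = %.4g\n",
                  d, k, cs[[k]]$n_edges, length(cs[[k]]$nodes),
                  cs[[k]]$strength, cs[[k]]$p_fwe))
  }
  invisible(x)
}

#' @export
summary.nbs_glm <- function(object, ...) {
  rows <- list()
  for (d in names(object$components)) for (k in seq_along(object$components[[d]])) {
    cc <- object$components[[d]][[k]]
    rows[[length(rows) + 1L]] <- data.frame(
      direction = d, component = k, n_edges = cc$n_edges,
      n_nodes = length(cc$nodes), strength = cc$strength, p_fwe = cc$p_fwe,
      nodes = paste(cc$nodes, collapse = ","), stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(direction = character(), component = integer(),
               n_edges = integer(), n_nodes = integer(), strength = numeric(),
               p_fwe = numeric(), nodes = character())
  class(out) <- c("summary.nbs_glm", class(out))
  out
}

#' @export
plot.nbs_glm <- function(x, direction = names(x$components)[1], ...) {
  nm <- x$null_max[, direction]
  graphics::hist(nm, breaks = 30, col = "grey85", border = "white",
                 main = paste("Null max component strength (", direction, ")"),
                 xlab = "max component strength",
                 xlim = range(c(nm, vapply(x$components[[direction]],
                                           `[[`, numeric(1), "strength"), 1)))
  for (cc in x$components[[direction]])
    graphics::abline(v = cc$strength, col = "firebrick", lwd = 2)
  invisible(x)
}
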