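# Shared fixtures and independent oracles (kept deliberately naive: these
# re-derive results by brute force, not through the package's own code paths).

# Connected components by boolean reachability (adjacency-matrix closure).
brute_components <- function(ei, ej, n_nodes) {
  A <- diag(n_nodes) > 0
  for (k in seq_along(ei)) { A[ei[k], ej[k]] <- TRUE; A[ej[k], ei[k]] <- TRUE }
  for (m in seq_len(n_nodes)) A <- (A %*% A) > 0   # transitive closure
  # label each edge by the reachability class of its first endpoint
  classes <- apply(A, 1, function(r) paste(which(r), collapse = ","))
  classes[ei]
}

# Partial correlations by explicit residual regression for every pair.
partial_corr_bruteforce <- function(series) {
  p <- ncol(series)
  out <- diag(p)
  for (i in 1:(p - 1)) for (j in (i + 1):p) {
    others <- series[, -c(i, j), drop = FALSE]
    X <- cbind(1, others)
    ri <- series[, i] - X %*% qr.coef(qr(X), series[, i])
    rj <- series[, j] - X %*% qr.coef(qr(X), series[, j])
    out[i, j] <- out[j, i] <- cor(ri, rj)
  }
  out
}

# Transform a data matrix so its *sample* correlation matrix equals R exactly.
make_exact_corr_data <- function(n, R, seed = 1) {
  set.seed(seed)
  p <- ncol(R)
  X <- matrix(rnorm(n * p), n, p)
  X <- scale(X, center = TRUE, scale = FALSE)
  X <- X %*% solve(chol(cov(X)))   # whiten (sample covariance = I)
  X %*% chol(R)
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# A small longitudinal cohort through the full time-series pathway.
tiny_cohort_stack <- function(seed = 1, n_rois = 6, n_subjects = 8,
                              n_volumes = 150, ...) {
  cfg <- synthetic_config(n_subjects = n_subjects,
                          n_female = floor(n_subjects / 2),
                          n_rois = n_rois, rois = paste0("R", seq_len(n_rois)),
                          n_volumes = n_volumes, missing_sessions = NULL,
                          seed = seed, ...)
  connectome_stack(generate_cohort(cfg)$panel)
}

# Random graph on n nodes as an edge list drawn from the complete graph.
random_graph <- function(n_nodes, p_edge, seed) {
  set.seed(seed)
  map <- edge_index_map(n_nodes)
  keep <- runif(nrow(map)) < p_edge
  map[keep, , drop = FALSE]
}
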