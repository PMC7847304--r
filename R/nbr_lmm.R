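# Longitudinal network-based statistics: edge-wise linear mixed models,
# suprathreshold components at an edge-level alpha, and permutation FWE on
# component strength with exchangeability restricted by the random-effects
# grouping (session labels are permuted within subjects for within-subject
# terms; sex labels across subjects for the between-subject term).
#
# The permutation engine (src/) refits a random-intercept REML model for
# every edge and permutation; observed and permuted statistics come from the
# same engine, which is what makes the FWE comparison exchangeable.

#' Long-format edge table of a connectome stack
#'
#' @param stack A [connectome_stack].
#' @return data.frame with columns `subject`, `sex`, `session`, `edge`,
#'   `label`, `z` (one row per dataset x edge).
#' @export
edge_long_table <- function(stack) {
  stopifnot(inherits(stack, "connectome_stack"))
  n <- nrow(stack$z); E <- ncol(stack$z)
  data.frame(
    subject = rep(stack$subject, times = E),
    sex = rep(stack$sex, times = E),
    session = rep(stack$session, times = E),
    edge = rep(seq_len(E), each = n),
    label = rep(stack$edge_map$label, each = n),
    z = as.vector(stack$z),
    stringsAsFactors = FALSE
  )
}

#' Longitudinal network-based statistic via edge-wise linear mixed models
#'
#' For every edge, fits a linear mixed model (REML, random intercept per
#' subject) of the Fisher-z value on the fixed effects in `fixed`, and tests
#' each requested term with a Wald F at inner-outer degrees of freedom
#' (see [lmm_df]). Edges with term p below `alpha_edge` define a
#' suprathreshold graph whose connected components are scored by strength
#' (sum of the absolute signed z-equivalent statistics,
#' `sign(dominant contrast) * sqrt(F)`). Family-wise error corrected
#' component p-values come from the permutation distribution of the maximum
#' component strength, with the permutation scheme respecting the grouping:
#' session labels are shuffled within each subject for session and
#' interaction terms, sex labels are shuffled across subjects for the sex
#' term. The add-one estimator guarantees p >= 1/(n_perm + 1).
#'
#' @param stack A [connectome_stack], or a long data.frame as produced by
#'   [edge_long_table] (columns `subject`, `sex`, `session`, `edge`, `z`).
#' @param fixed One-sided formula over `sex` and `session`; default
#'   `~ sex + session`. `~ sex * session` adds the interaction;
#'   `~ session` drops sex (identical component machinery).
#' @param terms Character subset of `c("sex", "session", "interaction")` to
#'   test (default: all terms present in `fixed`).
#' @param alpha_edge Edge-level threshold on the term p-value (default 0.05).
#' @param n_perm Number of permutations (default 5000).
#' @param seed Integer seed for the permutation stream.
#' @return Object of class `nbr_lmm`: per-term edge statistics, components
#'   with FWE p-values, null distributions, and the data needed for
#'   [emm_posthoc] refits.
#' @export
nbr_lmm <- function(stack, fixed = ~ sex + session, terms = NULL,
                    alpha_edge = 0.05, n_perm = 5000, seed = NULL) {
  if (inherits(stack, "connectome_stack")) {
    long <- edge_long_table(stack)
    edge_map <- stack$edge_map
    Y <- stack$z
    subject <- stack$subject; session <- stack$session; sex <- stack$sex
  } else {
    long <- as.data.frame(stack)
    stopifnot(all(c("subject", "session", "edge", "z") %in% names(long)))
    E <- max(long$edge)
    key <- paste(long$subject, long$session)
    cells <- !duplicated(key)
    subject <- long$subject[cells]; session <- long$session[cells]
    sex <- if ("sex" %in% names(long)) long$sex[cells] else rep("F", sum(cells))
    Y <- matrix(NA_real_, sum(cells), E)
    Y[cbind(match(key, key[cells]), long$edge)] <- long$z
    if (anyNA(Y)) stop("long table has missing (cell, edge) combinations")
    # embed an arbitrary edge count in the smallest complete graph whose
    # upper triangle holds it (exact when the count is triangular)
    p <- ceiling((1 + sqrt(1 + 8 * E)) / 2)
    edge_map <- edge_index_map(as.integer(p))[seq_len(E), , drop = FALSE]
    if (!"label" %in% names(long))
      long$label <- edge_map$label[long$edge]
  }
  if (!"sex" %in% names(long)) long$sex <- "F"

  tl <- attr(stats::terms(fixed), "term.labels")
  bad <- setdiff(tl, c("sex", "session", "sex:session", "session:sex"))
  if (length(bad)) stop("unsupported fixed terms: ", paste(bad, collapse = ", "))
  include_sex <- "sex" %in% tl
  include_inter <- any(c("sex:session", "session:sex") %in% tl)
  if (!"session" %in% tl) stop("the session term is required")
  if (is.null(terms)) {
    terms <- c(if (include_sex) "sex", "session",
               if (include_inter) "interaction")
  }
  stopifnot(all(terms %in% c("sex", "session", "interaction")))
  if ("sex" %in% terms && !include_sex) stop("cannot test sex: not in fixed")
  if ("interaction" %in% terms && !include_inter)
    stop("cannot test interaction: not in fixed")
  if (!all(session %in% 1:3) || length(unique(session)) != 3)
    stop("the permutation engine expects a 3-level session design")

  n_obs <- nrow(Y)
  subj_f <- factor(subject)
  nsubj <- nlevels(subj_f)
  term_code <- c(sex = 0L, session = 1L, interaction = 2L)[terms]
  term_df1 <- c(sex = 1, session = 2, interaction = 2)[terms]
  df_terms <- ifelse(terms == "sex",
                     lmm_df(n_obs, nsubj, term_df1, within = FALSE),
                     lmm_df(n_obs, nsubj, term_df1, within = TRUE))

  if (!is.null(seed)) set.seed(seed)
  eng <- cpp_nbr_perm(Y, as.integer(session),
                      as.integer(sex == "M"),
                      as.integer(subj_f) - 1L, nsubj,
                      include_sex, include_inter,
                      term_code, df_terms, alpha_edge,
                      edge_map$i, edge_map$j, max(edge_map$j), n_perm)
  obs <- eng$observed
  null_max <- eng$null_max
  colnames(null_max) <- terms

  results <- list()
  for (k in seq_along(terms)) {
    pvec <- obs$p[, k]; zvec <- obs$z[, k]
    keep <- !is.na(pvec) & pvec < alpha_edge
    comps <- build_components(zvec, edge_map, keep)
    for (i in seq_along(comps))
      comps[[i]]$p_fwe <- (1 + sum(null_max[, k] >= comps[[i]]$strength)) /
        (1 + n_perm)
    results[[terms[k]]] <- list(
      stats = data.frame(edge = edge_map$edge, label = edge_map$label,
                         F = obs$F[, k], p = pvec, z = zvec,
                         df1 = unname(term_df1[k]), df2 = unname(df_terms[k]),
                         stringsAsFactors = FALSE),
      components = comps,
      excluded = which(is.na(pvec)))
  }

  structure(list(results = results, null_max = null_max,
                 alpha_edge = alpha_edge, n_perm = n_perm, seed = seed,
                 fixed = fixed, terms = terms, edge_map = edge_map,
                 n_obs = n_obs, n_subjects = nsubj,
                 data = long, call = match.call()),
            class = "nbr_lmm")
}

#' @export
print.nbr_lmm <- function(x, ...) {
  cat("Longitudinal network-based statistic (edge-wise LMM)\n")
  cat("  ", x$n_obs, " datasets, ", x$n_subjects, " subjects, ",
      nrow(x$edge_map), " edges; edge alpha ", x$alpha_edge, ", ",
      x$n_perm, " permutations\n", sep = "")
  for (tm in names(x$results)) {
    cs <- x$results[[tm]]$components
    if (!length(cs)) { cat("  ", tm, ": no suprathreshold component\n", sep = ""); next }
    for (k in seq_along(cs))
      cat(sprintf("  %s component %d: %d edges, %d nodes, strength %.2f, FWE p = %.4g\n",
                  tm, k, cs[[k]]$n_edges, length(cs[[k]]$nodes),
                  cs[[k]]$strength, cs[[k]]$p_fwe))
  }
  invisible(x)
}

#' @export
summary.nbr_lmm <- function(object, ...) {
  rows <- list()
  for (tm in names(object$results)) {
    cs <- object$results[[tm]]$components
    for (k in seq_along(cs))
      rows[[length(rows) + 1L]] <- data.frame(
        term = tm, component = k, n_edges = cs[[k]]$n_edges,
        n_nodes = length(cs[[k]]$nodes), strength = cs[[k]]$strength,
        p_fwe = cs[[k]]$p_fwe,
        nodes = paste(cs[[k]]$nodes, collapse = ","),
        stringsAsFactors = FALSE)
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(term = character(), component = integer(),
               n_edges = integer(), n_nodes = integer(),
               strength = numeric(), p_fwe = numeric(), nodes = character())
}

#' @export
plot.nbr_lmm <- function(x, term = names(x$results)[1], ...) {
  nm <- x$null_max[, term]
  graphics::hist(nm, breaks = 30, col = "grey85", border = "white",
                 main = paste("Null max component strength (", term, ")"),
                 xlab = "max component strength",
                 xlim = range(c(nm, vapply(x$results[[term]]$components,
                                           `[[`, numeric(1), "strength"), 1)))
  for (cc in x$results[[term]]$components)
    graphics::abline(v = cc$strength, col = "firebrick", lwd = 2)
  invisible(x)
}
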