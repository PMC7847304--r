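# Edge-level linear mixed models. One model per edge: fixed sex and session
# effects (optionally their interaction), random intercept per subject, and
# optionally random per-subject session deviations with diagonal covariance.
# Estimation is by REML through nlme; degrees of freedom follow the
# inner-outer rule (within-subject terms: n_obs - n_subjects - term df;
# between-subject terms: n_subjects - term df - 1), which reproduces the
# classic F(1,30) / F(2,56) layout of a 90-observation, 32-subject,
# 3-session design.

#' Inner-outer degrees of freedom for a model term
#'
#' @param n_obs Total observations.
#' @param n_subjects Number of subjects (grouping units).
#' @param term_df Numerator df of the term (e.g. 2 for a 3-level session).
#' @param within Is the term estimated within subjects (varies inside a
#'   subject) or between?
#' @return Denominator degrees of freedom.
#' @examples
#' lmm_df(90, 32, 2, within = TRUE)    # 56, the session / post hoc df
#' lmm_df(90, 32, 1, within = FALSE)   # 30, the sex df
#' @export
lmm_df <- function(n_obs, n_subjects, term_df, within = TRUE) {
  if (within) n_obs - n_subjects - term_df else n_subjects - term_df - 1
}

#' Fit the linear mixed model for one edge
#'
#' REML fit of `z ~ sex + session` (optionally `sex * session`) with a random
#' intercept and, by default, random per-subject session deviations with
#' diagonal covariance. If the richer random structure fails to converge the
#' model falls back to a random intercept only, with a warning and a flag.
#' Missing (subject, session) cells are handled by likelihood: subjects
#' contribute whatever sessions they have.
#'
#' @param data data.frame with columns `subject`, `session` (1-3), `z`, and
#'   `sex` when the sex term is requested; at most one row per
#'   (subject, session).
#' @param fixed One-sided formula built from `sex` and `session`
#'   (default `~ sex + session`).
#' @param random `"intercept_session"` (default) or `"intercept"`.
#' @return Object of class `edge_lmm`: the nlme fit, a term table with Wald F
#'   tests at inner-outer df, the signed z-equivalent statistic per term
#'   (`sign(dominant contrast) * sqrt(F)`), and bookkeeping fields.
#' @export
fit_edge_lmm <- function(data, fixed = ~ sex + session,
                         random = c("intercept_session", "intercept")) {
  random <- match.arg(random)
  stopifnot(all(c("subject", "session", "z") %in% names(data)))
  if (anyDuplicated(data[, c("subject", "session")]))
    stop("duplicated (subject, session) cells")
  if (sd(data$z) == 0) stop("degenerate edge: all values identical")
  tl <- attr(stats::terms(fixed), "term.labels")
  bad <- setdiff(tl, c("sex", "session", "sex:session", "session:sex"))
  if (length(bad)) stop("unsupported fixed terms: ", paste(bad, collapse = ", "))
  include_sex <- "sex" %in% tl
  include_inter <- any(c("sex:session", "session:sex") %in% tl)
  if (include_inter && !include_sex) stop("interaction requires the sex term")

  d <- data
  d$session <- factor(d$session, levels = sort(unique(data$session)))
  if (include_sex) d$sex <- factor(d$sex)
  d$subject <- factor(d$subject)
  if (length(levels(d$session)) < 2 ||
      sum(table(d$subject) >= 2) < 2)
    stop("need >= 2 sessions observed for >= 2 subjects")

  fixed_full <- stats::reformulate(tl, response = "z")
  ctrl <- nlme::lmeControl(opt = "optim", returnObject = FALSE,
                           maxIter = 100, msMaxIter = 100)
  fallback <- FALSE
  fit <- NULL
  if (random == "intercept_session") {
    fit <- tryCatch(
      nlme::lme(fixed_full, data = d,
                random = list(subject = nlme::pdDiag(~session)),
                method = "REML", control = ctrl),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit)) fallback <- TRUE
  }
  if (is.null(fit)) {
    fit <- tryCatch(
      nlme::lme(fixed_full, data = d, random = ~ 1 | subject,
                method = "REML", control = ctrl),
      error = function(e) stop("edge model failed to converge: ",
                               conditionMessage(e)))
    if (fallback)
      warning("random session-deviation structure did not converge; ",
              "fell back to random intercept only")
  }

  n_obs <- nrow(d); n_subj <- length(unique(d$subject))
  beta <- nlme::fixef(fit)
  V <- as.matrix(stats::vcov(fit))
  asg <- attr(stats::model.matrix(stats::delete.response(stats::terms(fixed_full)),
                                  d), "assign")
  term_table <- do.call(rbind, lapply(seq_along(tl), function(k) {
    idx <- which(asg == k)
    bt <- beta[idx]; Vt <- V[idx, idx, drop = FALSE]
    Fv <- drop(crossprod(bt, solve(Vt, bt))) / length(idx)
    within <- grepl("session", tl[k])
    df2 <- lmm_df(n_obs, n_subj, length(idx), within = within)
    tj <- bt / sqrt(diag(Vt))
    zeq <- sign(tj[which.max(abs(tj))]) * sqrt(Fv)
    data.frame(term = tl[k], df1 = length(idx), df2 = df2, F = Fv,
               p = pf(Fv, length(idx), df2, lower.tail = FALSE),
               z = unname(zeq), stringsAsFactors = FALSE)
  }))

  structure(list(fit = fit, terms = term_table, n_obs = n_obs,
                 n_subjects = n_subj, fixed = fixed_full,
                 random = if (fallback || random == "intercept")
                   "intercept" else random,
                 fallback = fallback, data = d),
            class = "edge_lmm")
}

#' @export
print.edge_lmm <- function(x, ...) {
  cat("Edge linear mixed model (REML, random ", x$random, ")\n", sep = "")
  cat("  ", x$n_obs, " observations, ", x$n_subjects, " subjects\n", sep = "")
  print(x$terms, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.edge_lmm <- function(object, ...) nlme::fixef(object$fit)

#' @export
summary.edge_lmm <- function(object, ...) {
  list(terms = object$terms, fixed = nlme::fixef(object$fit),
       sigma = object$fit$sigma, random = object$random)
}

#' @export
residuals.edge_lmm <- function(object, ...) stats::residuals(object$fit, ...)

# Session estimated marginal means and pairwise contrasts for one fitted edge.
# EMMs average the model's cell predictions over the levels of the other
# factor(s) with equal weights; df follows the within-subject rule.
session_contrasts <- function(fit_obj) {
  stopifnot(inherits(fit_obj, "edge_lmm"))
  fit <- fit_obj$fit
  d <- fit_obj$data
  tl <- attr(stats::terms(fit_obj$fixed), "term.labels")
  grid <- if ("sex" %in% tl)
    expand.grid(sex = levels(d$sex), session = levels(d$session))
  else expand.grid(session = levels(d$session))
  X <- stats::model.matrix(stats::delete.response(stats::terms(fit_obj$fixed)),
                           grid)
  beta <- nlme::fixef(fit)
  V <- as.matrix(stats::vcov(fit))
  L <- do.call(rbind, lapply(levels(d$session), function(s)
    colMeans(X[grid$session == s, , drop = FALSE])))
  rownames(L) <- levels(d$session)
  pairs <- utils::combn(levels(d$session), 2, simplify = FALSE)
  df2 <- lmm_df(fit_obj$n_obs, fit_obj$n_subjects,
                length(levels(d$session)) - 1, within = TRUE)
  do.call(rbind, lapply(pairs, function(pr) {
    l <- L[pr[1], ] - L[pr[2], ]
    est <- drop(l %*% beta)
    se <- drop(sqrt(l %*% V %*% l))
    tv <- est / se
    data.frame(contrast = paste(pr[1], "-", pr[2]), estimate = est, se = se,
               t = tv, df = df2, p = 2 * pt(-abs(tv), df2),
               stringsAsFactors = FALSE)
  }))
}

#' Estimated-marginal-means post hoc session contrasts with FDR correction
#'
#' For each fitted edge, computes the three pairwise session contrasts of the
#' estimated marginal means (model cell means averaged over the other
#' factors), with t statistics at the within-subject inner-outer df, and
#' applies Benjamini-Hochberg adjustment across *all* contrasts of the
#' family (one family per network component).
#'
#' @param fits A single `edge_lmm`, a (optionally named) list of them, or an
#'   [nbr_lmm] object (then `component` and `term` select the network whose
#'   edges are refitted).
#' @param component,term For the `nbr_lmm` interface: which term's component
#'   (default the first significant session component).
#' @param ... Passed to [fit_edge_lmm] when edges are refitted.
#' @return data.frame with columns `edge`, `contrast`, `estimate`, `se`, `t`,
#'   `df`, `p`, `p_fdr`.
#' @export
emm_posthoc <- function(fits, component = 1, term = "session", ...) {
  if (inherits(fits, "nbr_lmm")) {
    comp <- fits$results[[term]]$components[[component]]
    if (is.null(comp)) stop("no component ", component, " for term ", term)
    long <- fits$data
    fits <- lapply(comp$edges$edge, function(e)
      fit_edge_lmm(long[long$edge == e, , drop = FALSE],
                   fixed = fits$fixed, ...))
    names(fits) <- comp$edges$label
  }
  if (inherits(fits, "edge_lmm")) fits <- list(edge1 = fits)
  if (is.null(names(fits))) names(fits) <- paste0("edge", seq_along(fits))
  out <- do.call(rbind, lapply(names(fits), function(nm) {
    tab <- session_contrasts(fits[[nm]])
    cbind(edge = nm, tab, stringsAsFactors = FALSE)
  }))
  out$p_fdr <- p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}
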