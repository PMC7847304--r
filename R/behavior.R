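# Behavioral measures and statistics for pair-bonding assays.

#' Partner-preference index
#'
#' Time near the partner divided by total time near both social incentive
#' areas. Satisfies `ppi(a, b) + ppi(b, a) = 1`.
#'
#' @param time_partner,time_stranger Non-negative times (same units);
#'   vectorised.
#' @return Value(s) in `[0, 1]`; `NA` with a warning where both times are 0.
#' @export
partner_preference_index <- function(time_partner, time_stranger) {
  stopifnot(all(time_partner >= 0, na.rm = TRUE),
            all(time_stranger >= 0, na.rm = TRUE))
  tot <- time_partner + time_stranger
  if (any(tot == 0, na.rm = TRUE))
    warning("zero total social time: index undefined, returning NA")
  ifelse(tot == 0, NA_real_, time_partner / tot)
}

#' Huddling latency from a bout list
#'
#' Latency (minutes) to the first continuous side-to-side contact bout
#' lasting at least `min_bout` seconds; shorter bouts are ignored. Returns
#' `NA` when no qualifying bout occurs.
#'
#' @param contact_bouts Two-column matrix/data.frame of bout start and end
#'   times in seconds, non-overlapping and sorted; or an empty object.
#' @param min_bout Minimum qualifying bout duration, seconds (default 10).
#' @return Latency in minutes, or `NA`.
#' @export
huddle_latency <- function(contact_bouts, min_bout = 10) {
  if (is.null(contact_bouts) || NROW(contact_bouts) == 0) return(NA_real_)
  b <- as.matrix(contact_bouts)
  stopifnot(ncol(b) == 2)
  dur <- b[, 2] - b[, 1]
  if (any(dur < 0)) stop("negative bout duration")
  if (any(diff(b[, 1]) < 0)) stop("bouts must be sorted by start time")
  ok <- which(dur >= min_bout)
  if (!length(ok)) return(NA_real_)
  b[ok[1], 1] / 60
}

#' Mann-Whitney U test with the |Z|/sqrt(N) effect size
#'
#' U is computed from rank sums with midranks for ties; Z uses the
#' large-sample normal approximation with tie-corrected variance and *no*
#' continuity correction, and the effect size is `|Z| / sqrt(n_subjects)`
#' where `n_subjects` is the number of unique subjects contributing
#' observations (not necessarily `n1 + n2`: a paired-proportion comparison of
#' 32 subjects contributes 64 sample values but N = 32). The p-value uses the
#' requested tail; a continuity correction can be applied to the p-value path
#' only.
#'
#' @param x,y The two samples.
#' @param n_subjects Number of unique subjects behind the observations.
#' @param tail `"two.sided"` (default), `"less"` or `"greater"` (direction of
#'   `x` relative to `y`).
#' @param continuity Apply continuity correction to the p-value (never to the
#'   effect size); default `FALSE`.
#' @return List with `U`, `Z`, `p`, `r_effect`, `n1`, `n2`.
#' @seealso [mwu_effect_from_u] to reproduce the effect size from a printed U.
#' @export
mann_whitney_with_effect <- function(x, y, n_subjects,
                                     tail = c("two.sided", "less", "greater"),
                                     continuity = FALSE) {
  tail <- match.arg(tail)
  stopifnot(length(x) > 0, length(y) > 0)
  if (n_subjects <= 0) stop("n_subjects must be positive")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))  # midranks
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(c(x, y))
  n <- n1 + n2
  tiecor <- sum(ties^3 - ties) / (n * (n - 1))
  sigma <- sqrt(n1 * n2 / 12 * ((n + 1) - tiecor))
  Z <- if (sigma == 0) 0 else (U - mu) / sigma
  cc <- if (continuity && sigma > 0) 0.5 / sigma else 0
  p <- switch(tail,
    two.sided = 2 * pnorm(abs(Z) - cc, lower.tail = FALSE),
    greater = pnorm(Z - cc, lower.tail = FALSE),
    less = pnorm(Z + cc))
  p <- min(p, 1)
  list(U = U, Z = Z, p = p,
       r_effect = abs(Z) / sqrt(n_subjects), n1 = n1, n2 = n2)
}

#' Effect size from a printed U statistic
#'
#' Recomputes the effect size `|Z| / sqrt(n_subjects)` from a U value and the group
#' sizes, using the tie-free normal approximation without continuity
#' correction — the convention needed to reproduce published (U, r) pairs.
#'
#' @param U The U statistic.
#' @param n1,n2 Group sizes.
#' @param n_subjects Unique subjects (effect-size denominator is its square
#'   root).
#' @return List with `Z` and `r_effect`.
#' @examples
#' round(mwu_effect_from_u(378, 32, 32, 32)$r_effect, 2)  # 0.32
#' @export
mwu_effect_from_u <- function(U, n1, n2, n_subjects) {
  sigma <- sqrt(n1 * n2 * (n1 + n2 + 1) / 12)
  Z <- (U - n1 * n2 / 2) / sigma
  list(Z = Z, r_effect = abs(Z) / sqrt(n_subjects))
}

#' Edge-behavior correlation with closed-form p-value
#'
#' Pearson or Spearman correlation between per-subject edge values and a
#' behavioral measure, with `df = n - 2` and the two-tailed p from the
#' t-distribution (`t = r * sqrt(df) / sqrt(1 - r^2)`); for Spearman the
#' same t-approximation is applied to rho. Pairwise-complete observations.
#'
#' @param edge_values,behavior Numeric vectors of equal length.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return List with `r`, `df`, `t`, `p`.
#' @export
edge_behavior_correlation <- function(edge_values, behavior,
                                      method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ok <- complete.cases(edge_values, behavior)
  x <- edge_values[ok]; y <- behavior[ok]
  if (length(x) < 4) stop("need at least 4 paired observations")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance in input")
  r <- cor(x, y, method = method)
  df <- length(x) - 2
  if (abs(r) >= 1) {
    return(list(r = r, df = df, t = sign(r) * Inf, p = 0))
  }
  tv <- r * sqrt(df) / sqrt(1 - r^2)
  list(r = r, df = df, t = tv, p = 2 * pt(-abs(tv), df))
}

#' Retained-dataset accounting for a longitudinal cohort
#'
#' Counts the datasets remaining after exclusions (duplicate exclusion
#' entries collapse to one) and tabulates availability per session.
#'
#' @param n_subjects,sessions Design size.
#' @param exclusions `NULL` or a data.frame with columns `subject`, `session`
#'   (and optionally `reason`).
#' @return List with `retained` (count), `per_session` (named vector), and
#'   `exclusions` (the deduplicated table).
#' @examples
#' cohort_manifest(32, 3, default_missing_sessions())$retained  # 90
#' @export
cohort_manifest <- function(n_subjects, sessions, exclusions = NULL) {
  total <- n_subjects * sessions
  per_session <- setNames(rep(n_subjects, sessions), paste0("session", 1:sessions))
  if (is.null(exclusions) || nrow(exclusions) == 0)
    return(list(retained = total, per_session = per_session,
                exclusions = exclusions))
  stopifnot(all(c("subject", "session") %in% names(exclusions)))
  if (any(exclusions$subject < 1 | exclusions$subject > n_subjects) ||
      any(exclusions$session < 1 | exclusions$session > sessions))
    stop("exclusions reference cells outside the design")
  dedup <- exclusions[!duplicated(exclusions[, c("subject", "session")]), ,
                      drop = FALSE]
  tab <- table(factor(dedup$session, levels = 1:sessions))
  per_session <- per_session - as.integer(tab)
  list(retained = total - nrow(dedup), per_session = per_session,
       exclusions = dedup)
}
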