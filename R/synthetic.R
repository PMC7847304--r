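# Synthetic cohort generator. Latent structure is specified on the
# partial-correlation scale: a unit-diagonal precision matrix is built with
# off-diagonal entries -p_ij, so the true partial correlations of the
# generated multivariate Gaussian equal the requested values exactly.

#' Configuration for a synthetic longitudinal connectivity cohort
#'
#' Defaults emulate the study design the package is built around: 32 subjects
#' (16 female, 16 male), 3 scanning sessions, 16 ROIs, 300 retained volumes at
#' TR = 2 s, and a missingness pattern in which six subjects each lack one
#' session, leaving 90 of 96 datasets.
#'
#' @param n_subjects,n_female Cohort size and number of females (females are
#'   listed first).
#' @param n_rois Number of ROIs; `rois` gives their labels.
#' @param n_volumes Retained volumes per dataset.
#' @param tr Repetition time, seconds.
#' @param rois ROI labels (default [roi_set()] truncated/padded to `n_rois`).
#' @param session_effects `NULL` or a data.frame with columns `edge`
#'   (canonical edge id), `session` (1-3) and `shift`: additive shift on the
#'   latent partial correlation of that edge in that session.
#' @param behavior_couplings `NULL` or a data.frame with columns `edge`,
#'   `session`, `slope`, `noise_sd`: the behavioral variable is generated as
#'   `intercept + slope * mean(true Fisher z of the coupled edges) + noise`.
#'   All rows must share one `noise_sd`. Coupled edges receive a shared
#'   per-subject latent deviation (`subject_factor_sd`), which is what makes
#'   the behavior informative about individual connectivity.
#' @param subject_factor_sd SD of the shared per-subject deviation applied to
#'   coupled edges, on the partial-correlation scale.
#' @param behavior_intercept Intercept of the coupled behavioral variable
#'   (huddling latency, minutes).
#' @param missing_sessions data.frame with columns `subject` (index) and
#'   `session`, the (subject, session) cells that are not acquired. The
#'   default reproduces the study bookkeeping: two subjects missing the
#'   baseline session, two missing the 2-week session, and two baseline
#'   datasets failing quality control.
#' @param ar1 Optional lag-1 autocorrelation of the generated time series
#'   (default 0: rows i.i.d.; band-passed fMRI is autocorrelated, so this
#'   knob exists for sensitivity analyses).
#' @param seed Integer seed; identical seed and config give a bit-identical
#'   cohort.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_subjects = 32, n_female = n_subjects %/% 2,
                             n_rois = 16,
                             n_volumes = 300, tr = 2,
                             rois = NULL,
                             session_effects = NULL,
                             behavior_couplings = NULL,
                             subject_factor_sd = 0.15,
                             behavior_intercept = 70,
                             missing_sessions = default_missing_sessions(),
                             ar1 = 0, seed = 1) {
  if (is.null(rois)) {
    base <- roi_set("social")
    rois <- if (n_rois <= length(base)) base[seq_len(n_rois)] else
      c(base, paste0("R", seq_len(n_rois - length(base))))
  }
  stopifnot(length(rois) == n_rois, n_female <= n_subjects, n_volumes > n_rois + 2)
  n_edges <- n_rois * (n_rois - 1) / 2
  check_edges <- function(df, what) {
    if (is.null(df)) return(invisible())
    stopifnot(is.data.frame(df), all(c("edge", "session") %in% names(df)))
    if (any(df$edge < 1 | df$edge > n_edges))
      stop(what, ": edge ids must lie in 1..", n_edges)
    if (any(!df$session %in% 1:3)) stop(what, ": sessions must be in 1..3")
  }
  check_edges(session_effects, "session_effects")
  check_edges(behavior_couplings, "behavior_couplings")
  if (!is.null(behavior_couplings) &&
      length(unique(behavior_couplings$noise_sd)) > 1)
    stop("behavior_couplings must share a single noise_sd")
  if (!is.null(missing_sessions)) {
    stopifnot(all(c("subject", "session") %in% names(missing_sessions)))
    if (any(missing_sessions$subject < 1 |
            missing_sessions$subject > n_subjects))
      stop("missing_sessions references unknown subjects")
    missing_sessions <- unique(missing_sessions[, c("subject", "session")])
  }
  structure(list(n_subjects = n_subjects, n_female = n_female,
                 n_rois = n_rois, n_volumes = n_volumes, tr = tr, rois = rois,
                 session_effects = session_effects,
                 behavior_couplings = behavior_couplings,
                 subject_factor_sd = subject_factor_sd,
                 behavior_intercept = behavior_intercept,
                 missing_sessions = missing_sessions,
                 ar1 = ar1, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' @rdname synthetic_config
#' @export
default_missing_sessions <- function() {
  data.frame(subject = c(1L, 2L, 3L, 4L, 5L, 6L),
             session = c(1L, 1L, 3L, 3L, 1L, 1L),
             reason = c("missed acquisition", "missed acquisition",
                        "missed acquisition", "missed acquisition",
                        "signal loss", "signal loss"))
}

# Unit-diagonal precision matrix realising the requested partial correlations.
precision_from_partials <- function(partials) {
  omega <- -partials
  diag(omega) <- 1
  ch <- tryCatch(chol(omega), error = function(e) NULL)
  if (is.null(ch))
    stop("invalid latent structure: induced precision matrix is not positive definite")
  omega
}

#' Simulate one subject's ROI time series with known partial correlations
#'
#' Rows are draws from a zero-mean multivariate Gaussian whose true partial
#' correlations equal `latent_partials`; the construction scales a
#' unit-diagonal precision matrix, so the target is met exactly in
#' population. With `ar1 > 0` the innovations follow an AR(1) process in
#' time (cross-sectional structure unchanged).
#'
#' @param latent_partials Symmetric ROI x ROI matrix, unit diagonal; the
#'   induced precision matrix must be positive definite.
#' @param n_volumes Number of time points.
#' @param seed Optional integer seed (when `NULL`, the current RNG stream is
#'   used).
#' @param ar1 Lag-1 temporal autocorrelation (default 0).
#' @return time x ROI matrix.
#' @export
generate_subject_timeseries <- function(latent_partials, n_volumes,
                                        seed = NULL, ar1 = 0) {
  stopifnot(is.matrix(latent_partials),
            nrow(latent_partials) == ncol(latent_partials))
  if (max(abs(latent_partials - t(latent_partials))) > 1e-8)
    stop("latent_partials must be symmetric")
  if (any(abs(diag(latent_partials) - 1) > 1e-8))
    stop("latent_partials must have unit diagonal")
  if (!is.null(seed)) set.seed(seed)
  omega <- precision_from_partials(latent_partials)
  sigma <- cov2cor(solve(omega))
  p <- ncol(sigma)
  z <- matrix(rnorm(n_volumes * p), n_volumes, p)
  if (ar1 > 0) {
    z <- apply(z, 2, function(col)
      as.numeric(stats::filter(col, ar1, method = "recursive")))
    z <- z * sqrt(1 - ar1^2)  # keep unit marginal variance
  }
  out <- z %*% chol(sigma)
  colnames(out) <- colnames(latent_partials)
  out
}

# Latent partial-correlation matrix for one (subject, session).
latent_for_cell <- function(config, session, subject_dev) {
  p <- diag(config$n_rois) * 0
  diag(p) <- 1
  map <- edge_index_map(config$rois)
  se <- config$session_effects
  if (!is.null(se)) {
    rows <- se[se$session == session, , drop = FALSE]
    if (nrow(rows)) {
      p[cbind(map$i[rows$edge], map$j[rows$edge])] <-
        p[cbind(map$i[rows$edge], map$j[rows$edge])] + rows$shift
    }
  }
  bc <- config$behavior_couplings
  if (!is.null(bc) && subject_dev != 0) {
    rows <- bc[bc$session == session, , drop = FALSE]
    if (nrow(rows)) {
      p[cbind(map$i[rows$edge], map$j[rows$edge])] <-
        p[cbind(map$i[rows$edge], map$j[rows$edge])] + subject_dev
    }
  }
  p[lower.tri(p)] <- t(p)[lower.tri(p)]
  dimnames(p) <- list(config$rois, config$rois)
  p
}

#' Generate a synthetic longitudinal cohort with ground truth
#'
#' Produces (i) an `roi_panel`: one time x ROI matrix per retained
#' (subject, session) cell; (ii) a behavior table (partner-preference times
#' and index, percent social time, huddling and mating latencies), with the
#' coupled variable generated from the planted edge-behavior slopes; and
#' (iii) the ground truth needed by recovery tests (latent matrices, planted
#' edges, slopes, per-subject true Fisher-z values).
#'
#' @param config A [synthetic_config].
#' @return List of class `synthetic_cohort` with elements `panel`,
#'   `behavior`, `truth`, `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  ns <- config$n_subjects
  sex <- c(rep("F", config$n_female), rep("M", ns - config$n_female))
  ids <- sprintf("S%02d", seq_len(ns))
  map <- edge_index_map(config$rois)

  coupled <- !is.null(config$behavior_couplings)
  factor_dev <- if (coupled) rnorm(ns, 0, config$subject_factor_sd) else numeric(ns)

  miss <- config$missing_sessions
  missing_key <- if (is.null(miss)) character(0) else
    paste(miss$subject, miss$session)

  series <- list(); meta <- list(); truth_z <- list()
  for (s in seq_len(ns)) {
    for (ses in 1:3) {
      latent <- latent_for_cell(config, ses, factor_dev[s])
      if (coupled) {
        bc <- config$behavior_couplings
        rows <- bc[bc$session == ses, , drop = FALSE]
        if (nrow(rows))
          truth_z[[paste(s, ses)]] <-
            fisher_z(latent[cbind(map$i[rows$edge], map$j[rows$edge])])
      }
      if (paste(s, ses) %in% missing_key) next
      # rare large subject deviations can break positive definiteness of the
      # induced precision; shrink the deviation until the latent is valid
      dev <- factor_dev[s]
      for (tries in 1:20) {
        ok <- !inherits(tryCatch(precision_from_partials(latent),
                                 error = function(e) e), "error")
        if (ok) break
        dev <- 0.8 * dev
        latent <- latent_for_cell(config, ses, dev)
      }
      series[[length(series) + 1L]] <-
        generate_subject_timeseries(latent, config$n_volumes, ar1 = config$ar1)
      meta[[length(meta) + 1L]] <-
        data.frame(subject = ids[s], session = ses, sex = sex[s],
                   tr = config$tr, stringsAsFactors = FALSE)
    }
  }
  panel <- structure(list(series = series, meta = do.call(rbind, meta)),
                     class = "roi_panel")

  behavior <- generate_behavior_table(config, ids, sex, factor_dev, map)

  latents <- lapply(1:3, function(ses) latent_for_cell(config, ses, 0))
  truth <- list(
    latent = latents,
    session_effect_edges = unique(config$session_effects$edge),
    behavior_edges = unique(config$behavior_couplings$edge),
    slopes = config$behavior_couplings,
    subject_factor = setNames(factor_dev, ids),
    true_z = truth_z
  )
  structure(list(panel = panel, behavior = behavior, truth = truth,
                 config = config),
            class = "synthetic_cohort")
}

# Behavioral measurements: the coupled variable (huddling latency) follows the
# planted linear model; the remaining measures are drawn from distributions
# that match the field's typical ranges (3-h partner preference test, ~80% of
# time on social areas, preference index centred near 0.6).
generate_behavior_table <- function(config, ids, sex, factor_dev, map) {
  ns <- config$n_subjects
  total <- 180  # minutes, 3-h test
  social_frac <- rbeta(ns, 8, 2)
  ppi <- rbeta(ns, 2.6, 1.6)
  time_partner <- total * social_frac * ppi
  time_stranger <- total * social_frac * (1 - ppi)
  bc <- config$behavior_couplings
  if (!is.null(bc)) {
    zbar <- vapply(seq_len(ns), function(s) {
      zs <- unlist(lapply(seq_len(nrow(bc)), function(r) {
        latent <- latent_for_cell(config, bc$session[r], factor_dev[s])
        fisher_z(latent[map$i[bc$edge[r]], map$j[bc$edge[r]]])
      }))
      mean(bc$slope * zs)
    }, numeric(1))
    latency <- config$behavior_intercept + zbar +
      rnorm(ns, 0, bc$noise_sd[1])
  } else {
    latency <- rgamma(ns, shape = 4, scale = 17.5)  # mean ~70 min
  }
  data.frame(
    subject = ids, sex = sex,
    test_period = rep(c("48h", "72h"), length.out = ns),
    time_partner = time_partner, time_stranger = time_stranger,
    total_test_time = total,
    ppi = partner_preference_index(time_partner, time_stranger),
    percent_social_time = 100 * (time_partner + time_stranger) / total,
    huddling_latency = latency,
    mount_latency = ifelse(sex == "M", rgamma(ns, 2, scale = 33), NA_real_),
    intromission_latency = ifelse(sex == "M", rgamma(ns, 3, scale = 39), NA_real_),
    ejaculation_latency = ifelse(sex == "M", rgamma(ns, 3, scale = 42), NA_real_),
    lordosis_latency = ifelse(sex == "F", rgamma(ns, 2, scale = 11), NA_real_),
    stringsAsFactors = FALSE
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort: ", x$config$n_subjects, " subjects (",
      x$config$n_female, " F), 3 sessions, ", x$config$n_rois, " ROIs\n",
      sep = "")
  cat("Retained datasets: ", length(x$panel$series), " of ",
      3 * x$config$n_subjects, "\n", sep = "")
  invisible(x)
}

#' Simulate an edge-level longitudinal table directly
#'
#' Bypasses the time-series layer: Fisher-z edge values are drawn as
#' `subject intercept + session shift + sex effect + residual`. Useful for
#' mixed-model parameter-recovery and calibration checks where the
#' connectome-estimation noise model is not under study.
#'
#' @param n_subjects,n_female Cohort composition.
#' @param n_edges Number of edges.
#' @param subject_sd SD of the per-subject random intercept.
#' @param resid_sd Residual SD.
#' @param shifts Numeric length-3 vector of per-session means added to every
#'   edge, or an `n_edges` x 3 matrix (per-edge shifts).
#' @param sex_effect Additive effect for males (default 0).
#' @param missing Optional data.frame (`subject`, `session`) of dropped cells.
#' @param seed Optional seed.
#' @return data.frame with columns `subject`, `sex`, `session`, `edge`, `z`.
#' @export
simulate_edge_table <- function(n_subjects = 32, n_female = n_subjects %/% 2,
                                n_edges = 1,
                                subject_sd = 0.1, resid_sd = 0.15,
                                shifts = c(0, 0, 0), sex_effect = 0,
                                missing = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(dim(shifts)))
    shifts <- matrix(shifts, n_edges, 3, byrow = TRUE)
  sex <- c(rep("F", n_female), rep("M", n_subjects - n_female))
  ids <- sprintf("S%02d", seq_len(n_subjects))
  b0 <- matrix(rnorm(n_subjects * n_edges, 0, subject_sd), n_subjects, n_edges)
  grid <- expand.grid(subject = seq_len(n_subjects), session = 1:3)
  if (!is.null(missing))
    grid <- grid[!paste(grid$subject, grid$session) %in%
                   paste(missing$subject, missing$session), ]
  out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(k) {
    s <- grid$subject[k]; ses <- grid$session[k]
    data.frame(subject = ids[s], sex = sex[s], session = ses,
               edge = seq_len(n_edges),
               z = b0[s, ] + shifts[, ses] +
                 (sex[s] == "M") * sex_effect +
                 rnorm(n_edges, 0, resid_sd),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
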