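# End-to-end driver: simulate (or load) a cohort, build connectomes, run the
# cross-sectional and longitudinal network statistics and the behavioral
# tests, and write a versioned, machine-readable results directory. All
# randomness flows from the configured seed, so two runs with the same seed
# produce byte-identical summaries.

#' Run the full analysis pipeline
#'
#' Stages: simulate (or load) -> connectome -> network GLM (baseline edges
#' vs. huddling latency) -> longitudinal network LMM -> behavioral tests
#' (partner preference) -> optional dual regression. Each stage logs its
#' parameters and seed; a stage failure aborts with the failing stage named,
#' retaining results already written.
#'
#' @param config A [synthetic_config] (defines ROIs, thresholds inherit the
#'   package defaults below).
#' @param mode `"simulate"` (generate the cohort from `config`) or
#'   `"analyze"` (read one written by [write_cohort] from `input_dir`).
#' @param out_dir Results directory.
#' @param input_dir Cohort directory for `mode = "analyze"`.
#' @param t_thresh,alpha_edge,fdr_q,n_perm Analysis settings (defaults: 1.7,
#'   0.05, 0.05, 5000).
#' @param drop_volumes Initial volumes to discard; the synthetic generator
#'   emits retained volumes only, so the default is 0 for simulated input.
#' @param behavior_covariate Behavior column for the network GLM.
#' @param include_dualreg Also run a small dual-regression stage on
#'   synthetic group maps (default `FALSE`).
#' @return List with `stack`, `nbs`, `nbr`, `behavior_tests`, `summary`
#'   (also written to `out_dir/summary.json`).
#' @export
run_pipeline <- function(config = synthetic_config(),
                         mode = c("simulate", "analyze"),
                         out_dir = tempfile("netlong_results_"),
                         input_dir = NULL,
                         t_thresh = 1.7, alpha_edge = 0.05, fdr_q = 0.05,
                         n_perm = 5000, drop_volumes = 0,
                         behavior_covariate = "huddling_latency",
                         include_dualreg = FALSE) {
  mode <- match.arg(mode)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "pipeline.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  stage <- function(name, expr) {
    logf("[stage %s] start", name)
    out <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    logf("[stage %s] done", name)
    out
  }
  file.create(log_path)
  logf("netlong pipeline; seed=%d; mode=%s", config$seed, mode)

  cohort <- stage("simulate", {
    if (mode == "simulate") generate_cohort(config) else {
      if (is.null(input_dir)) stop("input_dir required in analyze mode")
      loaded <- read_cohort(input_dir)
      list(panel = loaded$panel, behavior = loaded$behavior, config = config)
    }
  })

  stack <- stage("connectome", {
    panel <- cohort$panel
    if (drop_volumes > 0)
      panel$series <- lapply(panel$series, drop_initial_volumes,
                             k = drop_volumes)
    connectome_stack(panel)
  })
  logf("connectome: %d datasets, %d edges", nrow(stack$z), ncol(stack$z))

  nbs <- stage("nbs-glm", {
    nbs_glm(stack, covariate = behavior_covariate, behavior = cohort$behavior,
            session = 1, t_thresh = t_thresh, n_perm = n_perm,
            seed = config$seed + 1L, direction = "both")
  })

  nbr <- stage("nbs-lmm", {
    nbr_lmm(stack, fixed = ~ sex + session, alpha_edge = alpha_edge,
            n_perm = n_perm, seed = config$seed + 2L)
  })

  behavior_tests <- stage("behavior", {
    b <- cohort$behavior
    prop_partner <- b$ppi
    prop_stranger <- 1 - b$ppi
    ppt <- mann_whitney_with_effect(prop_partner, prop_stranger,
                                    n_subjects = nrow(b), tail = "greater")
    mf <- mann_whitney_with_effect(b$ppi[b$sex == "M"], b$ppi[b$sex == "F"],
                                   n_subjects = nrow(b))
    list(ppt_partner_vs_stranger = ppt, ppi_male_vs_female = mf,
         median_ppi = median(b$ppi, na.rm = TRUE),
         mean_percent_social_time = mean(b$percent_social_time, na.rm = TRUE))
  })

  dualreg <- NULL
  if (include_dualreg) {
    dualreg <- stage("dualreg", {
      set.seed(config$seed + 3L)
      nvox <- 200; k <- 4
      maps <- matrix(rnorm(nvox * k), nvox, k)
      complete <- names(which(table(stack$subject) == 3))
      subj_maps <- function(ses) t(vapply(complete, function(s) {
        ts <- cohort$panel$series[[which(stack$subject == s &
                                           stack$session == ses)[1]]]
        y <- ts[, 1:k, drop = FALSE] %*% t(maps) +
          matrix(rnorm(nrow(ts) * nvox, 0, 0.5), nrow(ts), nvox)
        s1 <- dual_regression_stage1(maps, y)
        dual_regression_stage2(y, s1)[1, ]
      }, numeric(nvox)))
      paired_signflip_test(subj_maps(1), subj_maps(2), n_perm = min(n_perm, 500),
                           seed = config$seed + 4L)
    })
  }

  summary <- list(
    seed = config$seed,
    settings = list(t_thresh = t_thresh, alpha_edge = alpha_edge,
                    fdr_q = fdr_q, n_perm = n_perm),
    rois = stack$rois,
    edge_ids = stack$edge_map$label,
    n_datasets = nrow(stack$z),
    nbs_glm = summary(nbs),
    nbr_lmm = summary(nbr),
    behavior = behavior_tests
  )
  jsonlite::write_json(config_payload(config), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  summary$input_hash <- unname(tools::md5sum(file.path(out_dir, "config.json")))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  write_nbs_result(nbs, file.path(out_dir, "nbs_glm.json"))
  write_nbs_result(nbr, file.path(out_dir, "nbr_lmm.json"))
  logf("summary written")

  invisible(list(stack = stack, nbs = nbs, nbr = nbr,
                 behavior_tests = behavior_tests, dualreg = dualreg,
                 summary = summary, out_dir = out_dir))
}

config_payload <- function(config) {
  pl <- unclass(config)
  pl[!vapply(pl, is.null, logical(1))]
}
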