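test_that("the inner-outer df rule reproduces the classic layout", {
  expect_equal(lmm_df(90, 32, 2, within = TRUE), 56)
  expect_equal(lmm_df(90, 32, 1, within = FALSE), 30)
  expect_equal(lmm_df(96, 32, 2, within = TRUE), 62)
})

test_that("a fitted edge model carries the right df and matches nlme's", {
  long <- simulate_edge_table(n_subjects = 32, subject_sd = 0.12,
                              resid_sd = 0.1, shifts = c(0, 0.05, 0.1),
                              missing = default_missing_sessions(), seed = 41)
  f <- fit_edge_lmm(long, random = "intercept")
  expect_equal(f$n_obs, 90)
  expect_equal(f$terms$df2[f$terms$term == "session"], 56)
  expect_equal(f$terms$df2[f$terms$term == "sex"], 30)
  # nlme's own denominator df agree with the rule
  a <- anova(f$fit)
  expect_equal(a["session", "denDF"], 56)
  expect_equal(a["sex", "denDF"], 30)
  # z-equivalent is a signed sqrt(F)
  expect_equal(abs(f$terms$z), sqrt(f$terms$F), tolerance = 1e-12)
})

test_that("the fast REML engine agrees with per-edge nlme fits", {
  long <- simulate_edge_table(n_subjects = 20, n_female = 10, n_edges = 4,
                              subject_sd = 0.15, resid_sd = 0.08,
                              shifts = c(0, 0.06, 0.1), sex_effect = 0.05,
                              missing = data.frame(subject = c(1, 2),
                                                   session = c(1, 3)),
                              seed = 42)
  r <- nbr_lmm(long, fixed = ~ sex + session, n_perm = 100, seed = 1)
  for (e in 1:4) {
    f <- fit_edge_lmm(long[long$edge == e, ], random = "intercept")
    expect_equal(r$results$session$stats$F[e],
                 f$terms$F[f$terms$term == "session"], tolerance = 1e-3)
    expect_equal(r$results$sex$stats$F[e],
                 f$terms$F[f$terms$term == "sex"], tolerance = 1e-3)
  }
})

test_that("null data give estimates within sampling error of zero", {
  long <- simulate_edge_table(n_subjects = 32, subject_sd = 0,
                              resid_sd = 0.1, seed = 43)
  f <- fit_edge_lmm(long, random = "intercept")
  V <- as.matrix(vcov(f$fit))
  est <- coef(f)
  expect_true(all(abs(est[-1]) < 4 * sqrt(diag(V))[-1]))
})

test_that("EMMs equal arithmetic session means on balanced complete data", {
  long <- simulate_edge_table(n_subjects = 16, n_female = 8,
                              subject_sd = 0.2, resid_sd = 0.1,
                              shifts = c(0, 0.1, 0.25), seed = 44)
  f <- fit_edge_lmm(long, random = "intercept")
  ph <- emm_posthoc(f)
  m <- tapply(long$z, long$session, mean)
  expect_equal(ph$estimate[ph$contrast == "1 - 2"], unname(m[1] - m[2]),
               tolerance = 1e-8)
  expect_equal(ph$estimate[ph$contrast == "1 - 3"], unname(m[1] - m[3]),
               tolerance = 1e-8)
  # FDR adjustment is monotone in the raw p ordering
  expect_true(all(diff(ph$p_fdr[order(ph$p)]) >= -1e-15))
})

test_that("EMM contrasts agree with the emmeans package", {
  skip_if_not_installed("emmeans")
  long <- simulate_edge_table(n_subjects = 18, n_female = 9,
                              subject_sd = 0.15, resid_sd = 0.1,
                              shifts = c(0, 0.08, 0.2), sex_effect = 0.07,
                              seed = 45)
  f <- fit_edge_lmm(long, random = "intercept")
  ph <- netlong:::session_contrasts(f)
  em <- as.data.frame(emmeans::contrast(
    emmeans::emmeans(f$fit, "session", data = f$data), "pairwise",
    adjust = "none"))
  # emmeans writes "session1 - session2"; ours "1 - 2"
  expect_equal(ph$estimate, em$estimate, tolerance = 1e-6)
  expect_equal(ph$se, em$SE, tolerance = 1e-6)
})

test_that("a planted session shift lands in the estimate's neighbourhood", {
  long <- simulate_edge_table(n_subjects = 32, subject_sd = 0.1,
                              resid_sd = 0.15, shifts = c(0, 0, 0.3),
                              missing = default_missing_sessions(), seed = 46)
  f <- fit_edge_lmm(long)
  ph <- netlong:::session_contrasts(f)
  est <- -ph$estimate[ph$contrast == "1 - 3"]
  se <- ph$se[ph$contrast == "1 - 3"]
  expect_lt(abs(est - 0.3), 3 * se)
  expect_equal(ph$df, rep(56, 3))
})

test_that("degenerate and malformed inputs are refused", {
  long <- simulate_edge_table(n_subjects = 8, seed = 47)
  bad <- rbind(long, long[1, ])
  expect_error(fit_edge_lmm(bad), "duplicated")
  cst <- long; cst$z <- 1
  expect_error(fit_edge_lmm(cst), "identical")
  expect_error(fit_edge_lmm(long, fixed = ~ sex + session + weight),
               "unsupported")
})

test_that("the richer random structure falls back gracefully when it cannot fit", {
  # two sessions only per subject leave no room for per-subject session
  # deviations on top of a residual: expect either a clean fit or a fallback
  long <- simulate_edge_table(n_subjects = 6, n_female = 3, subject_sd = 0.05,
                              resid_sd = 0.1, seed = 48)
  long <- long[long$session != 2, ]
  f <- suppressWarnings(fit_edge_lmm(long, fixed = ~ session))
  expect_s3_class(f, "edge_lmm")
  expect_true(f$random %in% c("intercept", "intercept_session"))
})
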