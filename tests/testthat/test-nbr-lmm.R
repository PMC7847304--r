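test_that("the longitudinal network test is seed-reproducible", {
  long <- simulate_edge_table(n_subjects = 12, n_female = 6, n_edges = 10,
                              subject_sd = 0.1, resid_sd = 0.08,
                              shifts = c(0, 0.05, 0.12), seed = 51)
  a <- nbr_lmm(long, terms = "session", n_perm = 200, seed = 3)
  b <- nbr_lmm(long, terms = "session", n_perm = 200, seed = 3)
  expect_identical(a$null_max, b$null_max)
  expect_identical(summary(a), summary(b))
  s <- summary(a)
  if (nrow(s)) expect_true(all(s$p_fwe >= 1 / 201 & s$p_fwe <= 1))
})

test_that("stack input and long-table input give identical results", {
  st <- tiny_cohort_stack(seed = 52, n_rois = 5, n_subjects = 10,
                          n_volumes = 120)
  a <- nbr_lmm(st, terms = "session", n_perm = 150, seed = 4)
  b <- nbr_lmm(edge_long_table(st), terms = "session", n_perm = 150, seed = 4)
  expect_equal(a$results$session$stats, b$results$session$stats)
  expect_identical(a$null_max, b$null_max)
})

test_that("session Wald F equals the repeated-measures decomposition on balanced data", {
  long <- simulate_edge_table(n_subjects = 20, n_female = 10,
                              subject_sd = 0.2, resid_sd = 0.1,
                              shifts = c(0, 0.08, 0.12), seed = 53)
  f <- nbr_lmm(long, fixed = ~ session, terms = "session", n_perm = 100,
               seed = 1)
  Fw <- f$results$session$stats$F
  # classical two-way (subject x session) decomposition by hand
  w <- matrix(long$z[order(long$session, long$subject)], ncol = 3)
  gm <- mean(w); sm <- rowMeans(w); cm <- colMeans(w)
  ss_sess <- nrow(w) * sum((cm - gm)^2)
  ss_err <- sum((w - outer(sm, rep(1, 3)) - outer(rep(1, nrow(w)), cm) + gm)^2)
  F_rm <- (ss_sess / 2) / (ss_err / (2 * (nrow(w) - 1)))
  expect_equal(Fw, F_rm, tolerance = 1e-6)
})

test_that("permuting one term's labels leaves the other term's observed stats intact", {
  long <- simulate_edge_table(n_subjects = 14, n_female = 7, n_edges = 6,
                              subject_sd = 0.1, resid_sd = 0.1,
                              sex_effect = 0.08, shifts = c(0, 0.05, 0.1),
                              seed = 54)
  both <- nbr_lmm(long, terms = c("sex", "session"), n_perm = 120, seed = 9)
  sess_only <- nbr_lmm(long, terms = "session", n_perm = 120, seed = 9)
  sex_only <- nbr_lmm(long, terms = "sex", n_perm = 120, seed = 9)
  expect_equal(both$results$session$stats$F, sess_only$results$session$stats$F)
  expect_equal(both$results$sex$stats$F, sex_only$results$sex$stats$F)
})

test_that("dropping the sex term reuses the same component machinery", {
  long <- simulate_edge_table(n_subjects = 16, n_female = 8, n_edges = 10,
                              subject_sd = 0.12, resid_sd = 0.06,
                              shifts = rbind(matrix(0, 6, 3),
                                             matrix(rep(c(0, 0.08, 0.16),
                                                        each = 4), 4, 3)),
                              seed = 55)
  f <- nbr_lmm(long, fixed = ~ session, terms = "session", n_perm = 200,
               seed = 2)
  expect_s3_class(f, "nbr_lmm")
  s <- summary(f)
  if (nrow(s)) {
    expect_true(all(s$p_fwe >= 1 / 201))
    # components are edge-disjoint
    ed <- unlist(lapply(f$results$session$components,
                        function(c) c$edges$edge))
    expect_equal(anyDuplicated(ed), 0)
  }
})

test_that("the sex*session interaction can be modelled and tested", {
  long <- simulate_edge_table(n_subjects = 16, n_female = 8, n_edges = 4,
                              subject_sd = 0.1, resid_sd = 0.1, seed = 56)
  f <- nbr_lmm(long, fixed = ~ sex * session,
               terms = c("session", "interaction"), n_perm = 120, seed = 6)
  expect_named(f$results, c("session", "interaction"))
  expect_equal(f$results$interaction$stats$df2[1],
               lmm_df(48, 16, 2, within = TRUE))
})

test_that("posthoc contrasts on a detected component carry df and FDR", {
  long <- simulate_edge_table(n_subjects = 24, n_female = 12, n_edges = 6,
                              subject_sd = 0.1, resid_sd = 0.07,
                              shifts = rbind(matrix(c(0, 0.12, 0.2), 3, 3,
                                                    byrow = TRUE),
                                             matrix(0, 3, 3)),
                              missing = data.frame(subject = 1:2,
                                                   session = c(1, 3)),
                              seed = 57)
  f <- nbr_lmm(long, terms = "session", n_perm = 300, seed = 8)
  comps <- f$results$session$components
  expect_gt(length(comps), 0)
  ph <- emm_posthoc(f, component = 1, term = "session")
  expect_true(all(c("edge", "contrast", "estimate", "t", "df", "p", "p_fdr")
                  %in% names(ph)))
  expect_equal(nrow(ph), 3 * comps[[1]]$n_edges)
  expect_equal(unique(ph$df), lmm_df(nrow(long) / 6, 24, 2, within = TRUE))
  expect_true(all(ph$p_fdr >= ph$p - 1e-15))
})

test_that("malformed designs are rejected", {
  long <- simulate_edge_table(n_subjects = 8, n_edges = 3, seed = 58)
  expect_error(nbr_lmm(long, fixed = ~ sex), "session term is required")
  expect_error(nbr_lmm(long, fixed = ~ session, terms = "sex"), "cannot test")
  two <- long[long$session != 3, ]
  expect_error(nbr_lmm(two, terms = "session"), "3-level session")
})
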