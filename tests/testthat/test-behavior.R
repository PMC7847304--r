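test_that("the partner-preference index is a symmetric proportion", {
  expect_equal(partner_preference_index(90, 10), 0.9)
  expect_equal(partner_preference_index(7.3, 7.3), 0.5)
  set.seed(61)
  a <- runif(20, 0, 100); b <- runif(20, 0, 100)
  expect_equal(partner_preference_index(a, b) +
                 partner_preference_index(b, a), rep(1, 20))
  expect_warning(out <- partner_preference_index(0, 0), "undefined")
  expect_true(is.na(out))
  expect_error(partner_preference_index(-1, 5))
})

test_that("huddling latency applies the 10-second bout rule", {
  expect_equal(huddle_latency(cbind(300, 1200)), 5)
  expect_equal(huddle_latency(rbind(c(0, 8), c(1800, 2700))), 30)
  expect_true(is.na(huddle_latency(cbind(0, 9.99))))
  expect_true(is.na(huddle_latency(NULL)))
  expect_error(huddle_latency(cbind(10, 5)), "negative")
})

test_that("the effect-size convention reproduces all published (U, r) pairs jointly", {
  cases <- list(c(U = 378, n1 = 32, n2 = 32, r = 0.32),
                c(U = 121, n1 = 16, n2 = 16, r = 0.05),
                c(U = 118, n1 = 16, n2 = 16, r = 0.07),
                c(U = 119, n1 = 16, n2 = 16, r = 0.06))
  for (cs in cases) {
    got <- mwu_effect_from_u(cs["U"], cs["n1"], cs["n2"], n_subjects = 32)
    expect_equal(round(unname(got$r_effect), 2), unname(cs["r"]))
  }
})

test_that("the rank test matches its definition, wilcox.test, and rank invariance", {
  set.seed(62)
  x <- rnorm(15); y <- rnorm(18, 0.4)
  ours <- mann_whitney_with_effect(x, y, n_subjects = 33)
  wt <- wilcox.test(x, y, correct = FALSE, exact = FALSE)
  expect_equal(unname(ours$U), unname(wt$statistic))
  expect_equal(ours$p, wt$p.value, tolerance = 1e-10)
  # invariance under a strictly monotone transform of the pooled data
  tr <- function(v) exp(v) + v
  ours2 <- mann_whitney_with_effect(tr(x), tr(y), n_subjects = 33)
  expect_identical(ours$U, ours2$U)
  expect_identical(ours$Z, ours2$Z)
  # identical samples: centre of the null
  same <- mann_whitney_with_effect(x, x, n_subjects = 15)
  expect_equal(same$U, length(x)^2 / 2)
  expect_equal(same$Z, 0)
  expect_equal(same$r_effect, 0)
  # ties handled by midranks with the tie-corrected variance
  xt <- c(1, 2, 2, 3); yt <- c(2, 3, 3, 4)
  wt2 <- wilcox.test(xt, yt, correct = FALSE, exact = FALSE)
  ours3 <- mann_whitney_with_effect(xt, yt, n_subjects = 8)
  expect_equal(unname(ours3$U), unname(wt2$statistic))
  expect_equal(ours3$p, wt2$p.value, tolerance = 1e-10)
  # one-tailed option and continuity-corrected p path
  lo <- mann_whitney_with_effect(x, y, 33, tail = "less")
  expect_equal(lo$p, pnorm(lo$Z))
  cc <- mann_whitney_with_effect(x, y, 33, continuity = TRUE)
  expect_equal(cc$p, wilcox.test(x, y, correct = TRUE,
                                 exact = FALSE)$p.value, tolerance = 1e-10)
})

test_that("edge-behavior correlations use the closed-form t at n - 2 df", {
  # exact sample correlation -0.468 with n = 28
  R <- matrix(c(1, -0.468, -0.468, 1), 2)
  X <- make_exact_corr_data(28, R, seed = 63)
  ct <- edge_behavior_correlation(X[, 1], X[, 2])
  expect_equal(ct$r, -0.468, tolerance = 1e-10)
  expect_equal(ct$df, 26)
  expect_equal(ct$t, -2.70, tolerance = 0.005)
  expect_gt(ct$p, 0.010); expect_lt(ct$p, 0.013)
  # agreement with cor.test
  or <- cor.test(X[, 1], X[, 2])
  expect_equal(ct$p, or$p.value, tolerance = 1e-12)
  # brute-force covariance-formula oracle
  set.seed(64)
  a <- rnorm(40); b <- rnorm(40)
  r_brute <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(edge_behavior_correlation(a, b)$r, r_brute, tolerance = 1e-12)
  # spearman path matches cor.test's t approximation
  cs <- edge_behavior_correlation(a, b, method = "spearman")
  os <- cor.test(a, b, method = "spearman", exact = FALSE)
  expect_equal(cs$r, unname(os$estimate), tolerance = 1e-12)
  expect_equal(cs$p, os$p.value, tolerance = 1e-10)
  # collinear points hit the boundary
  col <- edge_behavior_correlation(1:4, 2 * (1:4) + 3)
  expect_equal(col$r, 1)
  expect_equal(col$p, 0)
  expect_error(edge_behavior_correlation(rep(1, 5), rnorm(5)), "variance")
})

test_that("cohort accounting matches the stated exclusions", {
  expect_equal(cohort_manifest(32, 3, default_missing_sessions())$retained, 90)
  expect_equal(cohort_manifest(32, 3, NULL)$retained, 96)
  all_out <- expand.grid(subject = 1:4, session = 1:3)
  expect_equal(cohort_manifest(4, 3, all_out)$retained, 0)
  # duplicates collapse
  dup <- data.frame(subject = c(1, 1), session = c(2, 2))
  expect_equal(cohort_manifest(5, 3, dup)$retained, 14)
  ps <- cohort_manifest(32, 3, default_missing_sessions())$per_session
  expect_equal(unname(ps), c(28, 32, 30))
  expect_error(cohort_manifest(4, 3, data.frame(subject = 5, session = 1)),
               "outside")
})
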