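test_that("identity latent structure yields near-zero partial correlations", {
  lat <- diag(16)
  ts <- generate_subject_timeseries(lat, 300, seed = 21)
  pc <- partial_correlation_matrix(ts)
  off <- pc[upper.tri(pc)]
  expect_lt(max(abs(off)), 0.25)
  expect_lt(abs(mean(off)), 0.05)
})

test_that("the generator is deterministic and validates its latent input", {
  lat <- diag(5); lat[1, 2] <- lat[2, 1] <- 0.4
  a <- generate_subject_timeseries(lat, 100, seed = 22)
  b <- generate_subject_timeseries(lat, 100, seed = 22)
  expect_identical(a, b)
  bad <- matrix(0.9, 4, 4); diag(bad) <- 1   # precision not PD
  expect_error(generate_subject_timeseries(bad, 50), "invalid latent structure")
  asym <- lat; asym[1, 2] <- 0
  expect_error(generate_subject_timeseries(asym, 50), "symmetric")
})

test_that("estimation error shrinks like 1/sqrt(n volumes)", {
  lat <- diag(4); lat[1, 2] <- lat[2, 1] <- 0.4
  err <- function(n, reps) mean(vapply(seq_len(reps), function(r) {
    abs(partial_correlation_matrix(
      generate_subject_timeseries(lat, n, seed = 300 + r))[1, 2] - 0.4)
  }, numeric(1)))
  ratio <- err(500, 25) / err(4500, 25)    # expect ~ sqrt(9) = 3
  expect_gt(ratio, 1.7)
  expect_lt(ratio, 5.5)
})

test_that("cohort bookkeeping matches the design minus missing cells", {
  coh <- generate_cohort(synthetic_config(seed = 23))
  expect_equal(length(coh$panel$series), 90)
  expect_equal(nrow(coh$panel$meta), 90)
  expect_equal(sum(coh$panel$meta$session == 1), 28)
  expect_equal(sum(coh$panel$meta$session == 3), 30)
  # arbitrary pattern
  miss <- data.frame(subject = c(1, 1, 7), session = c(1, 2, 3))
  coh2 <- generate_cohort(synthetic_config(n_subjects = 10, n_female = 5,
                                           n_rois = 4, n_volumes = 60,
                                           rois = paste0("R", 1:4),
                                           missing_sessions = miss, seed = 24))
  expect_equal(length(coh2$panel$series), 10 * 3 - 3)
  expect_error(synthetic_config(n_subjects = 4, missing_sessions =
                                  data.frame(subject = 9, session = 1)),
               "unknown subjects")
})

test_that("identical seed and config reproduce the cohort bit for bit", {
  cfg <- synthetic_config(n_subjects = 4, n_female = 2, n_rois = 4,
                          n_volumes = 50, rois = paste0("R", 1:4),
                          missing_sessions = NULL, seed = 25)
  a <- generate_cohort(cfg); b <- generate_cohort(cfg)
  expect_identical(a$panel$series, b$panel$series)
  expect_identical(a$behavior, b$behavior)
})

test_that("noise-free behavior coupling is perfectly correlated with true z", {
  cfg <- synthetic_config(
    n_subjects = 12, n_female = 6, n_rois = 5, n_volumes = 60,
    rois = paste0("R", 1:5), missing_sessions = NULL,
    behavior_couplings = data.frame(edge = 3, session = 1, slope = -2,
                                    noise_sd = 0),
    seed = 26)
  coh <- generate_cohort(cfg)
  truez <- vapply(1:12, function(s) coh$truth$true_z[[paste(s, 1)]],
                  numeric(1))
  expect_equal(abs(cor(coh$behavior$huddling_latency, truez)), 1,
               tolerance = 1e-12)
  expect_equal(sign(cor(coh$behavior$huddling_latency, truez)), -1)
})

test_that("a planted negative slope is detected a posteriori across seeds", {
  hits <- 0
  for (s in 1:100) {
    cfg <- synthetic_config(
      n_subjects = 32, n_female = 16, n_rois = 8, n_volumes = 200,
      rois = paste0("R", 1:8), missing_sessions = NULL,
      behavior_couplings = data.frame(edge = 5, session = 1, slope = -2,
                                      noise_sd = 0.05),
      seed = 400 + s)
    coh <- generate_cohort(cfg)
    st <- connectome_stack(coh$panel)
    z1 <- session_edges(st, 1)[, 5]
    ct <- edge_behavior_correlation(z1, coh$behavior$huddling_latency)
    if (ct$r < 0 && ct$p < 0.01) hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("configuration invariants are enforced", {
  expect_error(synthetic_config(n_female = 40), "n_female")
  expect_error(synthetic_config(session_effects =
                                  data.frame(edge = 500, session = 1,
                                             shift = 0.1)),
               "1..120", fixed = TRUE)
  expect_error(synthetic_config(behavior_couplings =
                                  data.frame(edge = c(1, 2), session = 1,
                                             slope = 1,
                                             noise_sd = c(0.1, 0.2))),
               "noise_sd")
})

test_that("the direct edge-table simulator honours its design arguments", {
  tab <- simulate_edge_table(n_subjects = 6, n_edges = 2, seed = 27,
                             missing = data.frame(subject = 1, session = 2))
  expect_equal(nrow(tab), (6 * 3 - 1) * 2)
  expect_equal(sort(unique(tab$edge)), 1:2)
  tab2 <- simulate_edge_table(n_subjects = 6, n_edges = 2, seed = 27,
                              missing = data.frame(subject = 1, session = 2))
  expect_identical(tab, tab2)
})
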