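test_that("edge T statistics match hand OLS and an lm() oracle", {
  # three points by hand: slope 0.5, r = 0.5, T = 0.5/sqrt(0.75) with df = 1
  tt <- edge_glm_stats(matrix(c(-1, 1, 0)), c(-1, 0, 1))
  expect_equal(unname(tt[1]), 0.5 * sqrt(1 / 0.75), tolerance = 1e-10)
  expect_equal(attr(tt, "df"), 1)

  set.seed(31)
  Y <- matrix(rnorm(28 * 120), 28, 120)
  x <- rnorm(28)
  tt <- edge_glm_stats(Y, x)
  for (e in c(1, 17, 60, 120)) {
    or <- summary(lm(Y[, e] ~ x))$coefficients["x", "t value"]
    expect_lt(abs(tt[e] - or), 1e-8)
  }
  # with a nuisance covariate
  nuis <- cbind(rnorm(28))
  tt2 <- edge_glm_stats(Y, x, nuis)
  or2 <- summary(lm(Y[, 3] ~ nuis + x))$coefficients["x", "t value"]
  expect_lt(abs(tt2[3] - or2), 1e-8)

  expect_error(edge_glm_stats(Y, rep(1, 28)), "constant covariate")
})

test_that("null edges give centred small T statistics", {
  set.seed(32)
  Y <- matrix(rnorm(40 * 200), 40, 200)
  tt <- edge_glm_stats(Y, rnorm(40))
  expect_lt(abs(mean(tt)), 0.2)
  expect_lt(mean(abs(tt) > 3), 0.02)
})

test_that("suprathreshold components match hand graphs and brute force", {
  map5 <- edge_index_map(5)
  stats <- rep(0, nrow(map5))
  pick <- function(i, j) map5$edge[map5$i == i & map5$j == j]
  stats[c(pick(1, 2), pick(2, 3), pick(4, 5))] <- c(2.1, 2.5, 3.0)
  comps <- threshold_and_components(stats, map5, 1.7, "positive")
  expect_equal(length(comps), 2)
  sizes <- vapply(comps, `[[`, integer(1), "n_edges")
  expect_setequal(sizes, c(2L, 1L))
  big <- comps[[which(sizes == 2)]]
  expect_equal(big$nodes, c("R1", "R2", "R3"))
  expect_equal(big$strength, 4.6)
  expect_equal(component_strength(big), 4.6)
  expect_equal(component_strength(comps[[which(sizes == 1)]]), 3.0)
  # negative direction takes absolute strengths
  compsn <- threshold_and_components(-stats, map5, 1.7, "negative")
  expect_equal(compsn[[which(vapply(compsn, `[[`, integer(1), "n_edges") == 1)]]$strength, 3.0)
  # nothing passes
  expect_identical(threshold_and_components(stats, map5, 5, "positive"), list())

  # brute-force agreement on random graphs up to 8 nodes
  for (s in 1:300) {
    n <- sample(2:8, 1)
    g <- random_graph(n, runif(1, 0.1, 0.6), seed = 5000 + s)
    if (nrow(g) == 0) next
    lab <- netlong:::cpp_edge_components(g$i, g$j, n)
    oracle <- brute_components(g$i, g$j, n)
    # identical partitions: each labelling refines the other
    expect_true(all(tapply(oracle, lab, function(v) length(unique(v))) == 1))
    expect_true(all(tapply(lab, oracle, function(v) length(unique(v))) == 1))
  }
})

test_that("the permutation FWE test is reproducible and sane", {
  set.seed(33)
  Y <- matrix(rnorm(24 * 45), 24, 45)
  x <- rnorm(24)
  a <- nbs_glm(Y, x, edge_map = edge_index_map(10), n_perm = 300, seed = 99)
  b <- nbs_glm(Y, x, edge_map = edge_index_map(10), n_perm = 300, seed = 99)
  expect_identical(a$null_max, b$null_max)
  expect_identical(summary(a)$p_fwe, summary(b)$p_fwe)

  # p bounds and monotonicity in strength for a fixed null
  s <- summary(a)
  if (nrow(s) > 1) {
    for (d in unique(s$direction)) {
      sd_ <- s[s$direction == d, ]
      expect_true(all(diff(sd_$p_fwe[order(-sd_$strength)]) >= 0))
    }
  }
  expect_true(all(s$p_fwe >= 1 / 301 & s$p_fwe <= 1))

  # raising the threshold never enlarges a component edge set
  hi <- nbs_glm(Y, x, edge_map = edge_index_map(10), t_thresh = 2.2,
                n_perm = 300, seed = 99)
  hi_edges <- unlist(lapply(hi$components$positive, function(c) c$edges$edge))
  lo_edges <- unlist(lapply(a$components$positive, function(c) c$edges$edge))
  expect_true(all(hi_edges %in% lo_edges))
})

test_that("Freedman-Lane nuisance permutation runs and stays in bounds", {
  set.seed(34)
  Y <- matrix(rnorm(26 * 21), 26, 21)
  x <- rnorm(26); z <- rnorm(26)
  fit <- nbs_glm(Y, x, nuisance = cbind(z), edge_map = edge_index_map(7),
                 n_perm = 200, seed = 5)
  s <- summary(fit)
  expect_true(all(s$p_fwe > 0 & s$p_fwe <= 1))
})

test_that("components agree with igraph on a larger random graph", {
  skip_if_not_installed("igraph")
  g <- random_graph(16, 0.15, seed = 77)
  lab <- netlong:::cpp_edge_components(g$i, g$j, 16)
  ig <- igraph::graph_from_edgelist(cbind(g$i, g$j), directed = FALSE)
  memb <- igraph::components(ig)$membership
  expect_equal(length(unique(lab)), length(unique(memb[g$i])))
  expect_true(all(tapply(memb[g$i], lab, function(v) length(unique(v))) == 1))
})
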