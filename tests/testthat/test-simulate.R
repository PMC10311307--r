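test_that("synthetic spatial graphs hit the target mean degree", {
  for (s in 1:3) {
    g <- synthetic_spatial_graph(300, n_samples = 2, mean_degree = 6, seed = s)
    realized <- 2 * nrow(g$edges) / g$n_nodes
    expect_lt(abs(realized - 6), 0.5)
    loc <- attr(g, "locations")
    expect_equal(nrow(loc), 600)
    expect_true(all(loc$x >= 0 & loc$x <= 1000))
    # edges respect the attached threshold and stay within samples
    thr <- attr(g, "threshold")
    d <- sqrt((loc$x[g$edges[, 1]] - loc$x[g$edges[, 2]])^2 +
                (loc$y[g$edges[, 1]] - loc$y[g$edges[, 2]])^2)
    expect_true(all(d < thr))
    expect_true(all(loc$sample_id[g$edges[, 1]] == loc$sample_id[g$edges[, 2]]))
  }
  expect_error(synthetic_spatial_graph(5, mean_degree = 10), "unreachable")
  g1 <- synthetic_spatial_graph(200, seed = 9)
  g2 <- synthetic_spatial_graph(200, seed = 9)
  expect_identical(g1$edges, g2$edges)
})

test_that("interaction regimes draw from the documented supports", {
  set.seed(111)
  for (i in 1:10) {
    b <- sample_interactions(8, "biased")$beta_s_vec
    u <- sample_interactions(8, "uniform")$beta_s_vec
    expect_true(all(b >= 0.7 & b <= 1))
    expect_true(all(u >= 0 & u <= 1))
  }
  # uniform draws do reach below 0.7 (would be impossible under biased)
  set.seed(112)
  many <- replicate(50, sample_interactions(8, "uniform")$beta_s_vec)
  expect_gt(mean(many < 0.7), 0.5)
  expect_error(sample_interactions(1, "biased"), "at least 2")
})

test_that("overlap estimate matches the 1-D two-component closed form", {
  # equal-variance 1-D components at distance delta: each misclassification
  # probability is Phi(-delta/2), so the pairwise overlap is 2 Phi(-delta/2)
  for (delta in c(1, 2, 3)) {
    spec <- mixture_spec(matrix(c(0, delta), 2, 1), matrix(1, 2, 1))
    est <- estimate_overlap(spec, n_mc = 4e4, seed = 113)
    expect_lt(abs(as.numeric(est) - 2 * pnorm(-delta / 2)), 0.012)
  }
  # overlap of nearly identical components approaches 1, and the pairwise
  # matrix is symmetric
  spec0 <- mixture_spec(matrix(c(0, 0.01, 0.02), 3, 2), matrix(1, 3, 2))
  est0 <- estimate_overlap(spec0, n_mc = 2000, seed = 114)
  expect_gt(as.numeric(est0), 0.9)
  pw <- attr(est0, "pairwise")
  expect_equal(pw, t(pw))
})

test_that("overlap calibration reaches the target within tolerance", {
  for (target in c(0.025, 0.125)) {
    spec <- calibrate_overlap(K = 4, M = 6, target, seed = 115)
    achieved <- attr(spec, "achieved_overlap")
    expect_lt(abs(achieved / target - 1), 0.1)
    # independent re-estimate with fresh draws agrees loosely
    fresh <- estimate_overlap(spec, n_mc = 2e4, seed = 116)
    expect_lt(abs(as.numeric(fresh) - target), 0.35 * target + 0.01)
  }
  # calibration is deterministic given the seed
  s1 <- calibrate_overlap(3, 4, 0.05, seed = 117)
  s2 <- calibrate_overlap(3, 4, 0.05, seed = 117)
  expect_identical(s1$means, s2$means)
  # larger radius means less overlap (monotonicity used by the bisection)
  u <- matrix(1, 2, 1)
  o_small <- estimate_overlap(mixture_spec(1 * rbind(0, u[1, ]), matrix(1, 2, 1)),
                              n_mc = 5000, seed = 118)
  o_large <- estimate_overlap(mixture_spec(4 * rbind(0, u[1, ]), matrix(1, 2, 1)),
                              n_mc = 5000, seed = 118)
  expect_gt(as.numeric(o_small), as.numeric(o_large))
  expect_error(calibrate_overlap(3, 4, 1.5, seed = 1), "between 0 and 1")
})

test_that("forward simulation draws labels before expression, reproducibly", {
  g <- synthetic_spatial_graph(200, mean_degree = 6, seed = 121)
  d1 <- simulate_forward(g, K = 4, M = 5, regime = "biased", seed = 122)
  d2 <- simulate_forward(g, K = 4, M = 5, regime = "biased", seed = 122)
  expect_identical(d1$true_labels, d2$true_labels)
  expect_identical(d1$expression$values, d2$expression$values)
  expect_equal(dim(d1$expression$values), c(200L, 5L))
  expect_true(all(d1$true_labels %in% 1:4))
  expect_true(all(d1$true_affinity$beta_s_vec >= 0.7))
  # biased regime yields spatially coherent fields: same-label edge fraction
  # well above the 1/K chance level
  e <- g$edges
  frac <- mean(d1$true_labels[e[, 1]] == d1$true_labels[e[, 2]])
  expect_gt(frac, 1 / 4 + 0.1)
  # expression actually depends on the labels
  m1 <- colMeans(d1$expression$values[d1$true_labels == 1, , drop = FALSE])
  m2 <- colMeans(d1$expression$values[d1$true_labels == 2, , drop = FALSE])
  expect_gt(max(abs(m1 - m2)), 0.2)
})

test_that("overlap-study simulation controls expression difficulty", {
  g <- synthetic_spatial_graph(250, mean_degree = 6, seed = 123)
  easy <- simulate_overlap_study(g, K = 4, M = 6, target_overlap = 0.01,
                                 regime = "biased", seed = 124)
  hard <- simulate_overlap_study(g, K = 4, M = 6, target_overlap = 0.3,
                                 regime = "biased", seed = 124)
  spec_easy <- attr(easy, "mixture_spec")
  spec_hard <- attr(hard, "mixture_spec")
  expect_gt(attr(spec_easy, "radius"), attr(spec_hard, "radius"))
  # a nonspatial mixture finds the easy one much more accurately
  v_easy <- v_measure(easy$true_labels,
                      fit_gmm_baseline(easy$expression, 4, seed = 125))$v
  v_hard <- v_measure(hard$true_labels,
                      fit_gmm_baseline(hard$expression, 4, seed = 125))$v
  expect_gt(v_easy, v_hard)
})

test_that("labelled pool has the documented composition and signatures", {
  pool <- simulate_labelled_pool(n_cells = 5000, seed = 126)
  expect_equal(dim(pool$expression), c(5000L, 13L))
  expect_equal(length(pool$population_names), 8L)
  expect_true(all(pool$labels %in% 1:8))
  # empirical proportions near the configured abundances
  props <- tabulate(pool$labels, 8) / 5000
  expect_lt(max(abs(props - c(0.25, 0.22, 0.15, 0.10, 0.12, 0.06, 0.04, 0.06))),
            0.03)
  # population means recover the signature matrix
  emp <- t(vapply(1:8, function(k) {
    colMeans(pool$expression[pool$labels == k, , drop = FALSE])
  }, numeric(13)))
  expect_lt(max(abs(emp - pool$means)), 0.1)
})

test_that("semireal assembly samples strata without replacement when possible", {
  pool <- list(expression = matrix(seq_len(40), 20, 2), labels = rep(1:2, each = 10))
  g <- path_graph(8)
  sim_labels <- c(1L, 1L, 1L, 2L, 2L, 2L, 2L, 2L)
  d <- assemble_semireal(pool$expression, pool$labels, g, sim_labels, seed = 127)
  # every node's profile comes from the matching stratum, no profile reused
  expect_true(all(d$expression$values[sim_labels == 1, 1] <= 10))
  expect_true(all(d$expression$values[sim_labels == 2, 1] > 10))
  expect_equal(anyDuplicated(d$expression$values[, 1]), 0L)
  expect_identical(d$true_labels, sim_labels)
  # exhausted stratum falls back to replacement with a warning
  small_pool <- matrix(1:4, 2, 2)
  expect_warning(
    d2 <- assemble_semireal(small_pool, c(1L, 1L), g, rep(1L, 8), seed = 128),
    "with replacement")
  expect_equal(nrow(d2$expression$values), 8L)
  expect_error(assemble_semireal(small_pool, c(1L, 1L), g, sim_labels),
               "no cells for label")
})

test_that("dataset CSV export round-trips through the readers", {
  g <- synthetic_spatial_graph(50, mean_degree = 4, seed = 129)
  d <- simulate_forward(g, K = 3, M = 2, regime = "biased", seed = 130)
  stem <- withr::local_tempfile()
  paths <- write_dataset_csv(d, stem)
  expr <- read_expression_csv(paths[1])
  expect_identical(expr$values, d$expression$values)
  truth <- read_labels_csv(paths[2], expr)
  expect_equal(as.integer(truth), d$true_labels)
  loc <- read_locations_csv(paths[3])
  expect_equal(loc$cell_id, expr$cell_ids)
  g2 <- read_edge_list_csv(paths[4], expr)
  expect_equal(g2$edges, g$edges)
})
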