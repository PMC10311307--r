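test_that("model state validates labels and tracks fixed cells", {
  aff <- affinity_params("0p", 3, 0.5)
  st <- model_state(c(1L, 3L, 2L), aff)
  expect_equal(st$fixed, rep(FALSE, 3))
  expect_error(model_state(c(1L, 4L), aff), "out of range")
  st2 <- model_state(c(1L, 2L), aff, fixed = c(TRUE, FALSE))
  expect_true(st2$fixed[1])
})

test_that("fixed labels are never resampled by the collapsed sweep", {
  set.seed(71)
  g <- path_graph(6)
  expr <- tiny_expr(matrix(rnorm(6), 6, 1))
  hyper <- emission_hyper(2, 1)
  st <- model_state(rep(1L, 6), affinity_params("0p", 2, 0.5),
                    fixed = c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE))
  for (i in 1:20) {
    st <- gibbs_update_labels(st, expr, g, hyper)
    expect_equal(st$labels[c(1, 4)], c(1L, 1L))
  }
})

test_that("incremental sweep statistics agree with the from-scratch audit", {
  set.seed(72)
  g <- synthetic_spatial_graph(80, mean_degree = 5, seed = 72)
  expr <- tiny_expr(matrix(rnorm(240), 80, 3))
  hyper <- emission_hyper(3, 3)
  hyper <- register_anchors(hyper,
                            anchor_set(matrix(rnorm(6), 2, 3), c(1L, 3L), 3))
  st <- model_state(sample.int(3, 80, TRUE), affinity_params("0p", 3, 0.5))
  before <- compute_stats(st$labels, expr, hyper)
  st <- gibbs_update_labels(st, expr, g, hyper, seed = 73)
  after <- compute_stats(st$labels, expr, hyper)
  # total mass is conserved; anchors persist in every cluster's totals
  expect_equal(sum(after$n), sum(before$n))
  expect_equal(colSums(after$sum), colSums(before$sum), tolerance = 1e-9)
  expect_true(all(after$n >= hyper$anchor_n))
})

test_that("collapsed Gibbs targets the exact label posterior (enumeration oracle)", {
  set.seed(74)
  g <- path_graph(4)
  expr <- tiny_expr(matrix(c(-1.2, -0.8, 0.9, 1.4), 4, 1))
  hyper <- emission_hyper(2, 1)
  params <- affinity_params("0p", 2, beta_s = 0.8)
  exact <- exact_label_posterior(g, expr, hyper, params)
  st <- model_state(c(1L, 1L, 2L, 2L), params)
  counts <- numeric(2^4)
  set.seed(75)
  n_draws <- 4e4
  for (i in seq_len(500 + n_draws)) {
    st <- gibbs_update_labels(st, expr, g, hyper)
    if (i > 500) {
      idx <- encode_labels(st$labels, 2)
      counts[idx] <- counts[idx] + 1
    }
  }
  emp <- counts / sum(counts)
  codes <- apply(exact$labelings, 1, encode_labels, K = 2)
  expect_lt(tv_dist(emp[codes], exact$prob), 0.02)
})

test_that("reflection folds proposals into the unit interval", {
  expect_equal(reflect_unit(0.3), 0.3)
  expect_equal(reflect_unit(1.2), 0.8)
  expect_equal(reflect_unit(-0.1), 0.1)
  expect_equal(reflect_unit(2.4), 0.4)
  x <- seq(-3, 3, by = 0.01)
  r <- reflect_unit(x)
  expect_true(all(r >= 0 & r <= 1))
})

test_that("DMH refuses the fixed variant and flags acceptance", {
  g <- path_graph(4)
  st0 <- model_state(c(1L, 1L, 2L, 2L), affinity_params("0p", 2, 0.5))
  expect_warning(out <- dmh_update_beta(st0, g, seed = 76), "no free affinity")
  expect_equal(out$labels, st0$labels)
  st1 <- model_state(c(1L, 1L, 2L, 2L), affinity_params("1p", 2, 0.5))
  out1 <- dmh_update_beta(st1, g, seed = 77)
  expect_type(attr(out1, "accepted"), "logical")
  expect_true(all(free_params(out1$affinity) >= 0 &
                    free_params(out1$affinity) <= 1))
})

test_that("DMH matches the grid-exact affinity posterior (oracle)", {
  # small graph, fixed label field X; the exact posterior over the shared
  # affinity is p(beta | X) proportional to exp(U(X; beta)) / Z(beta) on [0, 1]
  g <- graph_from_pairs(6, list(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(5, 6),
                                c(1, 6), c(2, 5)))
  x_obs <- c(1L, 1L, 1L, 2L, 2L, 2L)
  grid <- seq(0.0005, 0.9995, by = 0.001)
  log_post <- vapply(grid, function(b) {
    p <- affinity_params("1p", 2, beta_s = b)
    mrf_log_potential(x_obs, g, p) -
      log(enumerate_partition_function(g, p))
  }, numeric(1))
  w <- exp(log_post - max(log_post))
  cdf_grid <- cumsum(w) / sum(w)

  st <- model_state(x_obs, affinity_params("1p", 2, beta_s = 0.5))
  set.seed(78)
  n_draws <- 2e4
  draws <- numeric(n_draws)
  for (i in seq_len(2000 + n_draws)) {
    st <- dmh_update_beta(st, g)
    if (i > 2000) draws[i - 2000] <- free_params(st$affinity)
  }
  emp_cdf <- vapply(grid, function(b) mean(draws <= b), numeric(1))
  ks <- max(abs(emp_cdf - cdf_grid))
  expect_lt(ks, 0.05)
})

test_that("run_mcmc returns a well-formed, seed-deterministic trace", {
  set.seed(79)
  g <- synthetic_spatial_graph(60, mean_degree = 5, seed = 79)
  expr <- tiny_expr(matrix(rnorm(180), 60, 3))
  tr <- run_mcmc(expr, g, K = 3, variant = "kp", n_iters = 30, seed = 80)
  expect_s3_class(tr, "hmrf_trace")
  expect_equal(dim(tr$labels), c(30L, 60L))
  expect_equal(dim(tr$beta), c(30L, 3L))
  expect_true(all(tr$labels >= 1 & tr$labels <= 3))
  expect_true(all(tr$beta >= 0 & tr$beta <= 1))
  expect_length(tr$log_potential, 30)
  tr2 <- run_mcmc(expr, g, K = 3, variant = "kp", n_iters = 30, seed = 80)
  expect_identical(tr$labels, tr2$labels)
  expect_identical(tr$beta, tr2$beta)
  # 0p records the fixed affinity; 1p has a single learned column
  tr0 <- run_mcmc(expr, g, K = 3, variant = "0p", n_iters = 5, seed = 81)
  expect_true(all(tr0$beta == 0.5))
  tr1 <- run_mcmc(expr, g, K = 3, variant = "1p", n_iters = 5, seed = 81)
  expect_equal(ncol(tr1$beta), 1L)
  expect_error(run_mcmc(expr, path_graph(4), K = 3), "different numbers")
  expect_error(run_mcmc(expr, g, K = 1), "at least 2")
})

test_that("prior and anchor modes initialize at the maximum-predictive cluster", {
  set.seed(82)
  mu <- c(-4, 0, 4)
  lab_true <- rep(1:3, each = 20)
  expr <- tiny_expr(matrix(rnorm(60, mu[lab_true], 0.3), 60, 1))
  g <- graph_from_pairs(60, list())  # no edges: emission-only
  anchors <- anchor_set(matrix(rnorm(30, rep(mu, each = 10), 0.3), 30, 1),
                        rep(1:3, each = 10), K = 3)
  hyper <- register_anchors(emission_hyper(3, 1), anchors)
  init <- max.col(predictive_score_matrix(expr, hyper))
  expect_gt(mean(init == lab_true), 0.95)
  tr <- run_mcmc(expr, g, variant = "0p", mode = "anchor", anchors = anchors,
                 n_iters = 20, seed = 83)
  est <- last_sample_estimate(tr)
  expect_gt(v_measure(lab_true, est)$v, 0.95)
  expect_error(run_mcmc(expr, g, mode = "anchor"), "requires anchors")
  expect_error(run_mcmc(expr, g, mode = "prior"), "requires prior_matrix")
})

test_that("trace CSV persistence round-trips the sampled values", {
  set.seed(84)
  g <- path_graph(10)
  expr <- tiny_expr(matrix(rnorm(20), 10, 2))
  tr <- run_mcmc(expr, g, K = 2, variant = "1p", n_iters = 8, seed = 85)
  stem <- withr::local_tempfile()
  paths <- write_trace_csv(tr, stem)
  labs <- as.matrix(utils::read.csv(paths[1]))
  expect_equal(unname(labs), unname(tr$labels))
  beta <- as.matrix(utils::read.csv(paths[2]))
  expect_equal(unname(beta), unname(tr$beta), tolerance = 1e-12)
})
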