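test_that("Normal-Gamma posterior update matches hand computation", {
  prior <- normal_gamma(mu0 = 1, lambda0 = 2, alpha0 = 3, b0 = 4)
  y <- c(0, 2, 4)
  post <- posterior_params(prior, stats_from_values(y))
  # mu_n = (2*1 + 3*2)/(2+3) = 8/5; ss = 8; b_n = 4 + 4 + 2*3*(2-1)^2/(2*5)
  expect_equal(post$mu0, 8 / 5)
  expect_equal(post$lambda0, 5)
  expect_equal(post$alpha0, 3 + 3 / 2)
  expect_equal(post$b0, 4 + 4 + 6 / 10)
  # empty stats return the prior unchanged
  expect_equal(posterior_params(prior, suff_stats()), prior)
  expect_error(normal_gamma(lambda0 = 0), "positive")
})

test_that("incremental statistics equal batch statistics (property)", {
  set.seed(61)
  for (rep in 1:10) {
    y <- rnorm(20)
    s <- suff_stats()
    for (v in y) s <- update_stats(s, v, "add")
    drop <- sample.int(20, 7)
    for (v in y[drop]) s <- update_stats(s, v, "remove")
    ref <- stats_from_values(y[-drop])
    expect_equal(s$n, ref$n)
    expect_equal(s$sum, ref$sum, tolerance = 1e-12)
    expect_equal(s$sumsq, ref$sumsq, tolerance = 1e-12)
  }
  expect_error(update_stats(suff_stats(), 1, "remove"), "empty")
})

test_that("posterior predictive integrates to one and matches quadrature", {
  prior <- normal_gamma(0.3, 1.5, 2, 1.2)
  post <- posterior_params(prior, stats_from_values(c(-1, 0.5, 2, 2.5)))
  for (p in list(prior, post)) {
    total <- stats::integrate(function(y) exp(log_predictive(y, p)),
                              -Inf, Inf, rel.tol = 1e-10)$value
    expect_equal(total, 1, tolerance = 1e-8)
  }
  # quadrature oracle: integral of N(y | mu, 1/tau) over the NG density,
  # evaluated by 2-D quadrature over (mu, tau)
  p <- prior
  y0 <- 0.8
  inner <- function(tau) {
    vapply(tau, function(t) {
      stats::integrate(function(mu) {
        stats::dnorm(y0, mu, 1 / sqrt(t)) *
          stats::dnorm(mu, p$mu0, 1 / sqrt(p$lambda0 * t))
      }, -Inf, Inf, rel.tol = 1e-10)$value *
        stats::dgamma(t, p$alpha0, rate = p$b0)
    }, numeric(1))
  }
  oracle <- stats::integrate(inner, 0, Inf, rel.tol = 1e-8)$value
  expect_equal(exp(log_predictive(y0, p)), oracle, tolerance = 1e-6)
})

test_that("log marginal likelihood matches sequential-predictive chaining", {
  # p(y_1..y_n) = prod_i p(y_i | y_1..y_{i-1}) must equal the closed form
  set.seed(63)
  prior <- normal_gamma(0.2, 0.7, 1.4, 0.9)
  y <- rnorm(8, 1, 2)
  chained <- 0
  for (i in seq_along(y)) {
    post <- posterior_params(prior, stats_from_values(y[seq_len(i - 1)]))
    chained <- chained + log_predictive(y[i], post)
  }
  expect_equal(log_marginal_likelihood(y, prior), chained, tolerance = 1e-10)
  expect_equal(log_marginal_likelihood(numeric(0), prior), 0)
  # exchangeability: order must not matter
  expect_equal(log_marginal_likelihood(rev(y), prior),
               log_marginal_likelihood(y, prior), tolerance = 1e-10)
})

test_that("prior expression codes map to the documented percentiles", {
  set.seed(65)
  vals <- cbind(sort(rnorm(101, 5, 2)), sort(runif(101, 0, 10)))
  expr <- tiny_expr(vals)
  q <- apply(vals, 2, stats::quantile, probs = c(0.25, 0.5, 0.75), names = FALSE)
  codes <- rbind(c(0L, 2L), c(-1L, 1L))
  rownames(codes) <- c("popA", "popB")
  hyper <- encode_prior_matrix(codes, expr, lambda_informative = 1,
                               lambda_vague = 0.01)
  expect_equal(hyper$mu0, rbind(c(q[1, 1], q[3, 2]), c(0, q[2, 2])))
  expect_equal(hyper$lambda0, rbind(c(1, 1), c(0.01, 1)))
  expect_equal(hyper$cluster_names, c("popA", "popB"))
  expect_error(encode_prior_matrix(rbind(c(3L, 0L)), expr), "-1, 0, 1, 2")
  expect_error(encode_prior_matrix(rbind(0L), expr), "one column per marker")
})

test_that("prior matrix CSV is read and aligned to the query marker order", {
  expr <- tiny_expr(matrix(rnorm(10), 5, 2))
  expr$marker_names <- c("CD3", "CD19")
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("cluster,CD19,CD3", "T,0,2", "B,2,-1"), path)
  codes <- read_prior_matrix_csv(path, expr)
  expect_equal(colnames(codes), c("CD3", "CD19"))
  expect_equal(codes["T", ], c(CD3 = 2L, CD19 = 0L))
  expect_equal(codes["B", ], c(CD3 = -1L, CD19 = 2L))
  writeLines(c("cluster,CD19", "T,0"), path)
  expect_error(read_prior_matrix_csv(path, expr), "missing markers: CD3")
})

test_that("anchors contribute permanent sufficient statistics", {
  hyper <- emission_hyper(K = 3, M = 1)
  a <- anchor_set(matrix(c(1, 3), 2, 1), labels = c(2L, 2L), K = 3)
  h2 <- register_anchors(hyper, a)
  expect_equal(h2$anchor_n, c(0, 2, 0))
  expect_equal(h2$anchor_sum[2, 1], 4)
  expect_equal(h2$anchor_sumsq[2, 1], 10)
  # anchors shift the predictive toward their profile, for cluster 2 only
  expr <- tiny_expr(matrix(2, 1, 1))
  s0 <- predictive_score_matrix(expr, hyper)
  s2 <- predictive_score_matrix(expr, h2)
  expect_gt(s2[1, 2], s0[1, 2])
  expect_equal(s2[1, c(1, 3)], s0[1, c(1, 3)])
  # compute_stats audit includes the anchor contribution
  st <- compute_stats(labels = c(1L), expr, h2)
  expect_equal(st$n, c(1, 2, 0))
  expect_equal(st$sum[, 1], c(2, 4, 0))
  expect_error(anchor_set(matrix(1, 1, 1), labels = 5L, K = 3), "1..K")
})

test_that("anchor registration warns on grossly mismatched scales", {
  set.seed(67)
  expr <- tiny_expr(matrix(rnorm(60), 20, 3))
  hyper <- emission_hyper(3, 3)
  a_bad <- anchor_set(matrix(rnorm(9, 0, 100), 3, 3), c(1L, 2L, 3L), 3)
  expect_warning(register_anchors(hyper, a_bad, expr), "scale")
  a_ok <- anchor_set(matrix(rnorm(9), 3, 3), c(1L, 2L, 3L), 3)
  expect_silent(register_anchors(hyper, a_ok, expr))
})

test_that("anchors CSV round-trips through anchor_set", {
  expr <- tiny_expr(matrix(rnorm(10), 5, 2))
  expr$marker_names <- c("m1", "m2")
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("m2,m1,label", "0.5,1.5,1", "2.5,3.5,2"), path)
  a <- read_anchors_csv(path, expr, K = 2)
  expect_equal(a$expression[, 1], c(1.5, 3.5))
  expect_equal(a$labels, c(1L, 2L))
  writeLines(c("m1,m2", "1,2"), path)
  expect_error(read_anchors_csv(path, expr, 2), "label")
})
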