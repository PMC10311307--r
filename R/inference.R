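#' Initial sampler state
#'
#' @param labels Integer labels (1..K), one per graph node.
#' @param affinity An [affinity_params()].
#' @param fixed Optional logical vector marking cells whose labels are
#'   never resampled (defaults to none; anchors live outside the graph and
#'   enter through the emission hyperparameters instead).
#' @return An object of class `model_state`.
#' @export
model_state <- function(labels, affinity, fixed = NULL) {
  labels <- as.integer(labels)
  if (is.null(fixed)) fixed <- rep(FALSE, length(labels))
  if (any(labels < 1L) || any(labels > affinity$K)) stop("label out of range 1..K")
  structure(list(labels = labels, affinity = affinity,
                 fixed = as.logical(fixed), iteration = 0L),
            class = "model_state")
}

#' Sufficient statistics implied by a label field
#'
#' Recomputes from scratch the per-(cluster, marker) counts, sums and sums
#' of squares of the current assignment, including the permanent anchor
#' contributions. Used as the consistency audit for the incremental
#' statistics maintained inside the collapsed sweep.
#'
#' @param labels Integer labels.
#' @param expr An [expression_matrix()].
#' @param hyper An [emission_hyper()] grid.
#' @return List with `n` (length K), `sum` and `sumsq` (K x M).
#' @export
compute_stats <- function(labels, expr, hyper) {
  K <- hyper$K; M <- hyper$M
  n <- hyper$anchor_n
  s <- hyper$anchor_sum
  sq <- hyper$anchor_sumsq
  for (k in seq_len(K)) {
    rows <- expr$values[labels == k, , drop = FALSE]
    n[k] <- n[k] + nrow(rows)
    s[k, ] <- s[k, ] + colSums(rows)
    sq[k, ] <- sq[k, ] + colSums(rows^2)
  }
  list(n = n, sum = s, sumsq = sq)
}

#' One collapsed Gibbs sweep over cell labels
#'
#' Each non-fixed cell is removed from its cluster's sufficient statistics
#' and reassigned to cluster k with probability proportional to
#' `exp(sum over neighbours of beta[k, x_neighbour])` times the product
#' over markers of the Student-t posterior predictive of the cell's
#' expression under cluster k's current statistics. All probability
#' arithmetic is done in log space with log-sum-exp stabilization.
#'
#' @param state A [model_state()].
#' @param expr An [expression_matrix()].
#' @param graph A [neighbour_graph()].
#' @param hyper An [emission_hyper()] grid.
#' @param seed Optional integer seed.
#' @param adj Optional precomputed [adjacency_list()] (avoids rebuilding it
#'   in tight loops).
#' @return The updated `model_state`.
#' @export
gibbs_update_labels <- function(state, expr, graph, hyper, seed = NULL,
                                adj = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(adj)) adj <- adjacency_list(graph)
  B <- expand_affinity(state$affinity)
  state$labels <- cpp_collapsed_sweep(
    state$labels, adj, B, expr$values,
    hyper$anchor_n, hyper$anchor_sum, hyper$anchor_sumsq,
    hyper$mu0, hyper$lambda0, hyper$alpha0, hyper$b0, state$fixed)
  state$iteration <- state$iteration + 1L
  state
}

# fold a real number into [0, 1] by reflection at both boundaries
reflect_unit <- function(x) {
  x <- x %% 2
  ifelse(x > 1, 2 - x, x)
}

#' One double Metropolis-Hastings update of the affinity parameters
#'
#' The affinity posterior is doubly intractable: the MRF normalizing
#' constant Z(beta) cannot be evaluated. The double Metropolis-Hastings
#' move cancels it exactly by simulating an auxiliary label field X* at the
#' proposed beta* (a few MRF-only Gibbs sweeps started from the current
#' labels) and accepting with probability
#' `min(1, exp(U(X; beta*) + U(X*; beta) - U(X; beta) - U(X*; beta*)))`
#' where U is the MRF log potential. One free parameter, chosen uniformly
#' at random for the `"kp"` variant, is perturbed per call by a Gaussian
#' random walk reflected into \[0, 1\]; the Uniform(0,1) prior contributes
#' only this box constraint.
#'
#' @param state A [model_state()].
#' @param graph A [neighbour_graph()].
#' @param proposal_scale Random-walk standard deviation.
#' @param inner_sweeps Auxiliary-chain Gibbs sweeps at the proposed beta.
#' @param seed Optional integer seed.
#' @param adj Optional precomputed [adjacency_list()].
#' @return The updated `model_state` (with attribute `"accepted"`); for the
#'   `"0p"` variant a warning is emitted and the state is returned
#'   unchanged.
#' @export
dmh_update_beta <- function(state, graph, proposal_scale = 0.1,
                            inner_sweeps = 2L, seed = NULL, adj = NULL) {
  if (state$affinity$variant == "0p") {
    warning("variant '0p' has no free affinity parameters; state unchanged")
    return(state)
  }
  if (!is.null(seed)) set.seed(seed)
  if (is.null(adj)) adj <- adjacency_list(graph)
  theta <- free_params(state$affinity)
  j <- if (length(theta) > 1L) sample.int(length(theta), 1L) else 1L
  theta_star <- theta
  theta_star[j] <- reflect_unit(theta[j] + stats::rnorm(1L, 0, proposal_scale))
  prop <- set_free_params(state$affinity, theta_star)
  B <- expand_affinity(state$affinity)
  B_star <- expand_affinity(prop)
  x_aux <- cpp_potts_sweeps(state$labels, adj, B_star,
                            as.integer(inner_sweeps), FALSE)
  log_alpha <- cpp_log_potential(graph$edges, state$labels, B_star) +
    cpp_log_potential(graph$edges, x_aux, B) -
    cpp_log_potential(graph$edges, state$labels, B) -
    cpp_log_potential(graph$edges, x_aux, B_star)
  accepted <- log(stats::runif(1L)) < log_alpha
  if (accepted) state$affinity <- prop
  attr(state, "accepted") <- accepted
  state
}

#' Fit the spatial clustering model by MCMC
#'
#' Runs the full sampler: per iteration, `n_dmh` double
#' Metropolis-Hastings updates of the affinity parameters followed by one
#' collapsed Gibbs sweep over cell labels, recording the post-iteration
#' state. Three modes are supported:
#'
#' * `"unsupervised"` — vague shared emission priors, uniform random label
#'   initialization; summarize with [mpear_point_estimate()].
#' * `"prior"` — emission priors from a quaternary prior expression matrix
#'   (see [encode_prior_matrix()]); cells initialized at their
#'   maximum-predictive cluster; summarize with [last_sample_estimate()].
#' * `"anchor"` — default priors plus registered anchor profiles; same
#'   initialization and summary as prior mode.
#'
#' @param expr An [expression_matrix()].
#' @param graph A [neighbour_graph()] over the same cells.
#' @param K Number of clusters (at least 2). Inferred from the prior
#'   matrix / anchors when those are supplied.
#' @param variant Affinity parameterization: `"0p"`, `"1p"` or `"kp"`.
#' @param mode `"unsupervised"`, `"prior"` or `"anchor"`.
#' @param prior_matrix Quaternary K x M code matrix (prior mode).
#' @param anchors An [anchor_set()] (anchor mode).
#' @param hyper Optional [emission_hyper()] overriding the defaults.
#' @param n_iters Number of MCMC iterations (default 500).
#' @param burn_in_fraction Fraction of the trace discarded by the summary
#'   functions (default 0.5); recorded on the trace.
#' @param beta_s Fixed diagonal affinity for variant `"0p"` (default 0.5)
#'   and the initial value for `"1p"`.
#' @param n_dmh Affinity updates per iteration (default 5).
#' @param proposal_scale,inner_sweeps Double Metropolis-Hastings controls.
#' @param seed Master seed; the run is deterministic given it.
#' @return An object of class `hmrf_trace`: list with `labels`
#'   (n_iters x N integer matrix), `beta` (n_iters x n_free matrix of free
#'   affinity parameters; the fixed value for `"0p"`), `log_potential`,
#'   and the run configuration fields.
#' @export
run_mcmc <- function(expr, graph, K = NULL,
                     variant = c("kp", "0p", "1p"),
                     mode = c("unsupervised", "prior", "anchor"),
                     prior_matrix = NULL, anchors = NULL, hyper = NULL,
                     n_iters = 500L, burn_in_fraction = 0.5,
                     beta_s = 0.5, n_dmh = 5L,
                     proposal_scale = 0.1, inner_sweeps = 2L, seed = NULL) {
  variant <- match.arg(variant)
  mode <- match.arg(mode)
  stopifnot(inherits(expr, "expression_matrix"), inherits(graph, "neighbour_graph"))
  if (graph$n_nodes != nrow(expr$values)) {
    stop("graph and expression matrix describe different numbers of cells")
  }
  N <- nrow(expr$values); M <- ncol(expr$values)
  if (mode == "prior") {
    if (is.null(prior_matrix)) stop("prior mode requires prior_matrix")
    if (is.null(K)) K <- nrow(as.matrix(prior_matrix))
    if (K != nrow(as.matrix(prior_matrix))) {
      stop("prior matrix must have one row per cluster (K = ", K, ")")
    }
  }
  if (mode == "anchor") {
    if (is.null(anchors)) stop("anchor mode requires anchors")
    if (is.null(K)) K <- anchors$K
  }
  if (is.null(K) || K < 2L) stop("K must be at least 2")
  K <- as.integer(K)
  if (!is.null(seed)) set.seed(seed)

  if (is.null(hyper)) {
    hyper <- if (mode == "prior") {
      encode_prior_matrix(prior_matrix, expr)
    } else {
      emission_hyper(K, M)
    }
  }
  if (mode == "anchor") hyper <- register_anchors(hyper, anchors, expr)
  if (hyper$K != K || hyper$M != M) stop("emission hyperparameter grid has the wrong shape")

  affinity <- switch(variant,
    "0p" = affinity_params("0p", K, beta_s = beta_s),
    "1p" = affinity_params("1p", K, beta_s = beta_s),
    "kp" = affinity_params("kp", K, beta_s_vec = rep(0.5, K)))

  labels <- if (mode == "unsupervised") {
    sample.int(K, N, replace = TRUE)
  } else {
    max.col(predictive_score_matrix(expr, hyper))
  }
  state <- model_state(labels, affinity)
  adj <- adjacency_list(graph)

  n_free <- max(length(free_params(affinity)), 1L)
  trace_labels <- matrix(0L, n_iters, N)
  trace_beta <- matrix(NA_real_, n_iters, n_free)
  log_pot <- numeric(n_iters)

  for (it in seq_len(n_iters)) {
    if (variant != "0p") {
      for (j in seq_len(n_dmh)) {
        state <- dmh_update_beta(state, graph, proposal_scale, inner_sweeps,
                                 adj = adj)
      }
    }
    state <- gibbs_update_labels(state, expr, graph, hyper, adj = adj)
    trace_labels[it, ] <- state$labels
    trace_beta[it, ] <- if (variant == "0p") beta_s else free_params(state$affinity)
    log_pot[it] <- cpp_log_potential(graph$edges, state$labels,
                                     expand_affinity(state$affinity))
  }

  structure(list(labels = trace_labels, beta = trace_beta,
                 log_potential = log_pot,
                 K = K, variant = variant, mode = mode,
                 n_iters = as.integer(n_iters),
                 burn_in_fraction = burn_in_fraction,
                 cluster_names = hyper$cluster_names,
                 cell_ids = expr$cell_ids, sample_ids = expr$sample_ids),
            class = "hmrf_trace")
}

#' @export
print.hmrf_trace <- function(x, ...) {
  cat(sprintf("hmrf_trace: %d iterations, %d cells, K=%d, variant=%s, mode=%s\n",
              x$n_iters, ncol(x$labels), x$K, x$variant, x$mode))
  invisible(x)
}

#' Per-cell cluster scores under the (anchor-informed) emission priors
#'
#' Sum over markers of the log posterior predictive of each cell under
#' each cluster's prior (including any registered anchor statistics),
#' before any cells are assigned. Used to initialize prior/anchor-mode
#' runs at the maximum-predictive cluster.
#'
#' @param expr An [expression_matrix()].
#' @param hyper An [emission_hyper()] grid.
#' @return N x K matrix of summed log predictive scores.
#' @export
predictive_score_matrix <- function(expr, hyper) {
  N <- nrow(expr$values)
  scores <- matrix(0, N, hyper$K)
  for (k in seq_len(hyper$K)) {
    for (m in seq_len(hyper$M)) {
      prior <- normal_gamma(hyper$mu0[k, m], hyper$lambda0[k, m],
                            hyper$alpha0[k, m], hyper$b0[k, m])
      st <- suff_stats()
      st$n <- hyper$anchor_n[k]
      st$sum <- hyper$anchor_sum[k, m]
      st$sumsq <- hyper$anchor_sumsq[k, m]
      post <- posterior_params(prior, st)
      scores[, k] <- scores[, k] + log_predictive(expr$values[, m], post)
    }
  }
  scores
}

#' Write an MCMC trace to CSV files
#'
#' Plain-text persistence: `<stem>_labels.csv` (iterations x cells),
#' `<stem>_beta.csv` and `<stem>_logpotential.csv`.
#'
#' @param trace An `hmrf_trace`.
#' @param stem Output path stem.
#' @return The written paths, invisibly.
#' @export
write_trace_csv <- function(trace, stem) {
  paths <- paste0(stem, c("_labels.csv", "_beta.csv", "_logpotential.csv"))
  utils::write.csv(trace$labels, paths[1L], row.names = FALSE)
  utils::write.csv(trace$beta, paths[2L], row.names = FALSE)
  utils::write.csv(data.frame(log_potential = trace$log_potential),
                   paths[3L], row.names = FALSE)
  invisible(paths)
}
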