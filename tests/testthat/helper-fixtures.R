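# Shared fixtures: tiny graphs and expression tables built in code.

graph_from_pairs <- function(n, pairs, sample_of = rep("s1", n)) {
  edges <- if (length(pairs) == 0) matrix(integer(0), 0, 2) else
    matrix(unlist(pairs), ncol = 2, byrow = TRUE)
  neighbour_graph(n, edges, sample_of)
}

path_graph <- function(n) {
  graph_from_pairs(n, lapply(seq_len(n - 1), function(i) c(i, i + 1)))
}

triangle_graph <- function() graph_from_pairs(3, list(c(1, 2), c(2, 3), c(1, 3)))

cycle_graph <- function(n) {
  graph_from_pairs(n, c(lapply(seq_len(n - 1), function(i) c(i, i + 1)),
                        list(c(n, 1))))
}

tiny_expr <- function(values, sample_ids = NULL) {
  values <- as.matrix(values)
  if (is.null(sample_ids)) sample_ids <- rep("s1", nrow(values))
  expression_matrix(values, paste0("cell_", seq_len(nrow(values))), sample_ids,
                    paste0("m", seq_len(ncol(values))))
}

tv_dist <- function(p, q) 0.5 * sum(abs(p - q))

# encode a small label vector as an index for tabulation against enumeration
encode_labels <- function(labels, K) sum((labels - 1) * K^(seq_along(labels) - 1)) + 1

# exact posterior over all K^N labelings: p(X | Y) proportional to
# exp(U(X; beta)) * prod_{k,m} marginal likelihood of the cells assigned to k
exact_label_posterior <- function(graph, expr, hyper, params) {
  B <- expand_affinity(params)
  K <- nrow(B)
  N <- graph$n_nodes
  labelings <- as.matrix(expand.grid(rep(list(seq_len(K)), N)))
  logw <- apply(labelings, 1, function(lab) {
    lp <- mrf_log_potential(lab, graph, B)
    for (k in seq_len(K)) {
      for (m in seq_len(hyper$M)) {
        prior <- normal_gamma(hyper$mu0[k, m], hyper$lambda0[k, m],
                              hyper$alpha0[k, m], hyper$b0[k, m])
        lp <- lp + log_marginal_likelihood(expr$values[lab == k, m], prior)
      }
    }
    lp
  })
  w <- exp(logw - max(logw))
  list(labelings = labelings, prob = w / sum(w))
}

# empirical distribution over labelings from a systematic-sweep Gibbs chain
chain_label_distribution <- function(graph, params, n_draws, burn = 1000,
                                     seed = 1) {
  B <- expand_affinity(params)
  K <- nrow(B)
  adj <- adjacency_list(graph)
  set.seed(seed)
  lab <- sample.int(K, graph$n_nodes, replace = TRUE)
  counts <- numeric(K^graph$n_nodes)
  for (i in seq_len(burn + n_draws)) {
    lab <- hmrfclust:::cpp_potts_sweeps(lab, adj, B, 1L, FALSE)
    if (i > burn) {
      idx <- encode_labels(lab, K)
      counts[idx] <- counts[idx] + 1
    }
  }
  counts / sum(counts)
}
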