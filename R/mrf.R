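#' Affinity parameterizations of the cluster interaction matrix
#'
#' The label prior couples neighbouring cells through a symmetric K x K
#' affinity matrix. Three parameterizations are supported:
#'
#' * `"0p"` — classic Potts smoothing: a single fixed diagonal value
#'   `beta_s` (default 0.5), zero off-diagonals; no free parameters.
#' * `"1p"` — as `"0p"` but `beta_s` is learned (Uniform(0,1) prior).
#' * `"kp"` — per-cluster autonomous affinities `beta_s_vec[k]` on the
#'   diagonal; nonautonomous off-diagonals are derived as the average of the
#'   two complementary disaffinities, `((1 - beta_s_vec[k]) +
#'   (1 - beta_s_vec[l])) / 2`, so clusters with weak self-affinity attract
#'   other types. K free parameters, each with a Uniform(0,1) prior.
#'
#' @param variant One of `"0p"`, `"1p"`, `"kp"`.
#' @param K Number of clusters.
#' @param beta_s Scalar in \[0,1\] for variants `"0p"`/`"1p"`.
#' @param beta_s_vec Length-K vector in \[0,1\] for variant `"kp"`.
#' @return An object of class `affinity_params`.
#' @export
affinity_params <- function(variant = c("0p", "1p", "kp"), K,
                            beta_s = 0.5, beta_s_vec = NULL) {
  variant <- match.arg(variant)
  K <- as.integer(K)
  if (K < 1L) stop("K must be at least 1")
  if (variant == "kp") {
    if (is.null(beta_s_vec)) stop("variant 'kp' requires beta_s_vec")
    beta_s_vec <- as.numeric(beta_s_vec)
    if (length(beta_s_vec) != K) stop("beta_s_vec must have length K")
    if (any(beta_s_vec < 0 | beta_s_vec > 1)) stop("affinities must lie in [0, 1]")
    out <- list(variant = variant, K = K, beta_s_vec = beta_s_vec)
  } else {
    if (length(beta_s) != 1L || beta_s < 0 || beta_s > 1) {
      stop("beta_s must be a scalar in [0, 1]")
    }
    out <- list(variant = variant, K = K, beta_s = as.numeric(beta_s))
  }
  structure(out, class = "affinity_params")
}

#' @export
print.affinity_params <- function(x, ...) {
  if (x$variant == "kp") {
    cat(sprintf("affinity_params (kp, K=%d): beta_s = %s\n", x$K,
                paste(signif(x$beta_s_vec, 3), collapse = ", ")))
  } else {
    cat(sprintf("affinity_params (%s, K=%d): beta_s = %g\n", x$variant, x$K, x$beta_s))
  }
  invisible(x)
}

#' Free parameters of an affinity object
#'
#' @param params An [affinity_params()].
#' @return Numeric vector of the learnable entries: empty for `"0p"`,
#'   `beta_s` for `"1p"`, `beta_s_vec` for `"kp"`.
#' @export
free_params <- function(params) {
  switch(params$variant,
         "0p" = numeric(0),
         "1p" = params$beta_s,
         "kp" = params$beta_s_vec)
}

#' Replace the free parameters of an affinity object
#'
#' @param params An [affinity_params()].
#' @param values Replacement vector, same length as [free_params()].
#' @return A new `affinity_params` object.
#' @export
set_free_params <- function(params, values) {
  switch(params$variant,
         "0p" = {
           if (length(values) != 0L) stop("variant '0p' has no free parameters")
           params
         },
         "1p" = affinity_params("1p", params$K, beta_s = values),
         "kp" = affinity_params("kp", params$K, beta_s_vec = values))
}

#' Expand affinity parameters to the full K x K matrix
#'
#' @param params An [affinity_params()].
#' @return Symmetric K x K numeric matrix with entries in \[0,1\].
#' @export
expand_affinity <- function(params) {
  stopifnot(inherits(params, "affinity_params"))
  K <- params$K
  if (params$variant == "kp") {
    d <- 1 - params$beta_s_vec
    B <- outer(d, d, function(a, b) (a + b) / 2)
    diag(B) <- params$beta_s_vec
  } else {
    B <- diag(params$beta_s, K)
  }
  B
}

#' Log potential of a label field under the MRF prior
#'
#' The unnormalized label prior places weight `exp(sum over edges of
#' beta[x_u, x_v])` on a labelling; this returns that sum, with each
#' unordered edge counted exactly once.
#'
#' @param labels Integer label vector (values in 1..K), one per graph node.
#' @param graph A [neighbour_graph()].
#' @param params An [affinity_params()] or an expanded K x K matrix.
#' @return The log unnormalized prior weight.
#' @export
mrf_log_potential <- function(labels, graph, params) {
  B <- if (inherits(params, "affinity_params")) expand_affinity(params) else params
  labels <- as.integer(labels)
  if (length(labels) != graph$n_nodes) stop("labels must cover every graph node")
  if (any(labels < 1L) || any(labels > nrow(B))) stop("label out of range 1..K")
  if (nrow(graph$edges) == 0L) return(0)
  cpp_log_potential(graph$edges, labels, B)
}

#' One Gibbs sweep over labels under the MRF prior alone
#'
#' Resamples each node from its full conditional `p(x_n = k | x_neighbours)
#' proportional to exp(sum over neighbours of beta[k, x_neighbour])`. The
#' sweep is in-place in the sense that later nodes see the updated labels of
#' earlier nodes. Used by the forward simulator and by the auxiliary chains
#' of the double Metropolis-Hastings affinity update.
#'
#' @param labels Integer start labels (1..K).
#' @param graph A [neighbour_graph()].
#' @param params [affinity_params()] or expanded matrix.
#' @param n_sweeps Number of systematic sweeps (ascending node index).
#' @param seed Optional integer seed.
#' @param random_scan If `TRUE`, nodes are picked uniformly at random
#'   (N draws per sweep) instead of systematically.
#' @return The updated integer label vector.
#' @export
mrf_gibbs_sweep <- function(labels, graph, params, n_sweeps = 1L, seed = NULL,
                            random_scan = FALSE) {
  B <- if (inherits(params, "affinity_params")) expand_affinity(params) else params
  labels <- as.integer(labels)
  if (length(labels) != graph$n_nodes) stop("labels must cover every graph node")
  if (any(labels < 1L) || any(labels > nrow(B))) stop("label out of range 1..K")
  if (!is.null(seed)) set.seed(seed)
  cpp_potts_sweeps(labels, adjacency_list(graph), B, as.integer(n_sweeps),
                   isTRUE(random_scan))
}

#' Simulate a label field from the MRF prior
#'
#' Initializes labels uniformly at random and applies `n_sweeps` Gibbs
#' sweeps, returning the final field.
#'
#' @param graph A [neighbour_graph()].
#' @param params [affinity_params()] or expanded matrix.
#' @param n_sweeps Number of sweeps (default 100).
#' @param seed Optional integer seed.
#' @return Integer label vector of length `graph$n_nodes`.
#' @export
simulate_labels <- function(graph, params, n_sweeps = 100L, seed = NULL) {
  B <- if (inherits(params, "affinity_params")) expand_affinity(params) else params
  if (n_sweeps < 1L) stop("n_sweeps must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  K <- nrow(B)
  init <- sample.int(K, graph$n_nodes, replace = TRUE)
  cpp_potts_sweeps(init, adjacency_list(graph), B, as.integer(n_sweeps), FALSE)
}

#' Exact partition function of the MRF prior by enumeration
#'
#' Sums the unnormalized weight over all K^N labelings. Only feasible for
#' tiny graphs; intended as an exact oracle for testing samplers.
#'
#' @param graph A [neighbour_graph()].
#' @param params [affinity_params()] or expanded matrix.
#' @param return_distribution If `TRUE`, also return every labelling with
#'   its exact probability.
#' @return The partition function `Z`, or (with
#'   `return_distribution = TRUE`) a list with `Z`, `labelings` (K^N x N
#'   integer matrix) and `prob`.
#' @export
enumerate_partition_function <- function(graph, params,
                                         return_distribution = FALSE) {
  B <- if (inherits(params, "affinity_params")) expand_affinity(params) else params
  K <- nrow(B)
  N <- graph$n_nodes
  if (K^N > 1e6) {
    stop("K^N exceeds 1e6; exact enumeration is an oracle for tiny graphs only")
  }
  grids <- rep(list(seq_len(K)), N)
  labelings <- as.matrix(expand.grid(grids, KEEP.OUT.ATTRS = FALSE))
  dimnames(labelings) <- NULL
  logw <- apply(labelings, 1L, function(lab) mrf_log_potential(lab, graph, B))
  mx <- max(logw)
  w <- exp(logw - mx)
  Z <- sum(w) * exp(mx)
  if (!return_distribution) return(Z)
  list(Z = Z, labelings = labelings, prob = w / sum(w))
}

#' Write a label field to CSV
#'
#' @param labels Integer labels.
#' @param expr The companion [expression_matrix()] supplying cell and
#'   sample identifiers.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labels_csv <- function(labels, expr, path) {
  utils::write.csv(data.frame(cell_id = expr$cell_ids,
                              sample_id = expr$sample_ids,
                              cluster = as.integer(labels)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a label field from CSV
#'
#' @param path CSV with columns `cell_id` and `cluster` (and optionally
#'   `sample_id`).
#' @param expr Optional [expression_matrix()]; when given, labels are
#'   aligned to its canonical cell order.
#' @return Integer label vector.
#' @export
read_labels_csv <- function(path, expr = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("cell_id", "cluster") %in% names(df))) {
    stop("labels CSV must contain columns cell_id and cluster")
  }
  if (!is.null(expr)) {
    idx <- match(expr$cell_ids, df$cell_id)
    if (anyNA(idx)) stop("labels missing for some cells")
    df <- df[idx, , drop = FALSE]
  }
  as.integer(df$cluster)
}
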