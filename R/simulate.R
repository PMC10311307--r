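#' Synthetic random-geometric spatial graph
#'
#' Stand-in for tissue neighbour graphs: per sample, `n_cells` cells are
#' placed uniformly at random in a square region (side 1000 pixels) and
#' joined by thresholded-distance edges, with the threshold tuned by
#' bisection so the realized mean degree approximates the target. Random
#' geometric graphs of mean degree ~6 mimic the density of segmented
#' tissue-region neighbour graphs.
#'
#' @param n_cells Cells per sample.
#' @param n_samples Number of disconnected sample components.
#' @param mean_degree Target mean degree (default 6).
#' @param seed Optional integer seed.
#' @param tol Acceptable absolute deviation of realized from target mean
#'   degree (default 0.5).
#' @return A [neighbour_graph()] with the generating [cell_locations()]
#'   attached as attribute `"locations"` and the tuned threshold as
#'   attribute `"threshold"`.
#' @export
synthetic_spatial_graph <- function(n_cells, n_samples = 1L, mean_degree = 6,
                                    seed = NULL, tol = 0.5) {
  if (n_cells < 1L) stop("n_cells must be at least 1")
  if (mean_degree >= n_cells) stop("mean degree unreachable: must be below n_cells")
  if (!is.null(seed)) set.seed(seed)
  side <- 1000
  N <- n_cells * n_samples
  xs <- stats::runif(N, 0, side)
  ys <- stats::runif(N, 0, side)
  sample_id <- rep(paste0("sample_", seq_len(n_samples)), each = n_cells)
  sample_code <- rep(seq_len(n_samples), each = n_cells)

  # pairwise within-sample distances, computed once; bisect the threshold
  d <- unlist(lapply(seq_len(n_samples), function(s) {
    idx <- which(sample_code == s)
    as.numeric(stats::dist(cbind(xs[idx], ys[idx])))
  }))
  degree_at <- function(t) 2 * sum(d < t) / N
  lo <- 0; hi <- side * sqrt(2)
  if (degree_at(hi) < mean_degree - tol) {
    stop("mean degree unreachable even with a maximal threshold")
  }
  thr <- hi
  for (i in seq_len(60L)) {
    mid <- (lo + hi) / 2
    if (degree_at(mid) < mean_degree) lo <- mid else hi <- mid
    thr <- hi
  }
  realized <- degree_at(thr)
  if (abs(realized - mean_degree) > max(tol, 4 / sqrt(N))) {
    stop(sprintf("bisection reached mean degree %.2f (target %.2f)",
                 realized, mean_degree))
  }
  loc <- cell_locations(paste0("cell_", seq_len(N)), sample_id, xs, ys)
  g <- build_neighbour_graph(loc, thr)
  attr(g, "locations") <- loc
  attr(g, "threshold") <- thr
  g
}

#' Draw cluster interaction parameters
#'
#' Per-cluster autonomous affinities for the `"kp"` parameterization under
#' the two study regimes: `"uniform"` draws each `beta_k^s` from
#' Uniform(0, 1), so autonomous and nonautonomous interactions are equally
#' likely to dominate; `"biased"` draws from Uniform(0.7, 1), making cells
#' of the same cluster prefer to neighbour each other.
#'
#' @param K Number of clusters (at least 2).
#' @param regime `"biased"` or `"uniform"`.
#' @param seed Optional integer seed.
#' @return An [affinity_params()] of variant `"kp"`.
#' @export
sample_interactions <- function(K, regime = c("biased", "uniform"), seed = NULL) {
  regime <- match.arg(regime)
  if (K < 2L) stop("K must be at least 2")
  if (!is.null(seed)) set.seed(seed)
  lo <- if (regime == "biased") 0.7 else 0
  affinity_params("kp", K, beta_s_vec = stats::runif(K, lo, 1))
}

#' Diagonal Gaussian mixture specification
#'
#' @param means K x M matrix of component means.
#' @param variances K x M matrix of positive per-dimension variances.
#' @return An object of class `mixture_spec`.
#' @export
mixture_spec <- function(means, variances) {
  means <- as.matrix(means); variances <- as.matrix(variances)
  if (!all(dim(means) == dim(variances))) stop("means and variances must match in shape")
  if (any(variances <= 0)) stop("variances must be positive")
  structure(list(means = means, variances = variances,
                 K = nrow(means), M = ncol(means)),
            class = "mixture_spec")
}

#' Monte-Carlo estimate of average pairwise component overlap
#'
#' Pairwise overlap between components k and l is the sum of the two
#' misclassification probabilities under equal priors: the probability that
#' a draw from k has higher density under l, plus the converse. Estimated
#' by Monte Carlo from `n_mc` draws per component and direction.
#'
#' @param spec A [mixture_spec()].
#' @param n_mc Draws per (component, direction).
#' @param seed Optional integer seed.
#' @return Average pairwise overlap, with the full pairwise matrix attached
#'   as attribute `"pairwise"`.
#' @export
estimate_overlap <- function(spec, n_mc = 4000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  K <- spec$K; M <- spec$M
  omega <- matrix(0, K, K)
  log_dens <- function(x, k) {
    # x: n x M draws; diagonal Gaussian log density of component k
    -0.5 * rowSums(sweep(sweep(x, 2L, spec$means[k, ])^2, 2L,
                         spec$variances[k, ], "/")) -
      0.5 * sum(log(spec$variances[k, ]))
  }
  for (k in seq_len(K - 1L)) {
    for (l in (k + 1L):K) {
      for (pair in list(c(k, l), c(l, k))) {
        a <- pair[1L]; b <- pair[2L]
        z <- matrix(stats::rnorm(n_mc * M), n_mc, M)
        x <- sweep(sweep(z, 2L, sqrt(spec$variances[a, ]), "*"), 2L,
                   spec$means[a, ], "+")
        omega[k, l] <- omega[k, l] + mean(log_dens(x, b) > log_dens(x, a))
      }
      omega[l, k] <- omega[k, l]
    }
  }
  avg <- mean(omega[upper.tri(omega)])
  attr(avg, "pairwise") <- omega
  avg
}

#' Calibrate a Gaussian mixture to a target average overlap
#'
#' Component means are placed at `radius * u_k` for fixed random unit
#' directions `u_k` with unit diagonal variances; the radius is tuned by
#' bisection until the Monte-Carlo estimate of the average pairwise
#' overlap is within `rel_tol` (relative) of the target. Overlap decreases
#' monotonically in the radius, so bisection converges whenever the target
#' is attainable for the drawn directions.
#'
#' @param K,M Component and dimension counts.
#' @param target_avg_overlap Target average pairwise overlap in (0, 1).
#' @param seed Optional integer seed (fixes both the directions and the
#'   Monte-Carlo draws, making calibration deterministic).
#' @param n_mc Monte-Carlo draws per component pair and direction.
#' @param rel_tol Relative tolerance on the achieved overlap (default 0.1).
#' @param max_iter Bisection iterations before giving up.
#' @return A [mixture_spec()] with attributes `"achieved_overlap"` and
#'   `"radius"`.
#' @export
calibrate_overlap <- function(K, M, target_avg_overlap, seed = NULL,
                              n_mc = 4000L, rel_tol = 0.1, max_iter = 40L) {
  if (target_avg_overlap <= 0 || target_avg_overlap >= 1) {
    stop("target_avg_overlap must lie strictly between 0 and 1")
  }
  if (!is.null(seed)) set.seed(seed)
  u <- matrix(stats::rnorm(K * M), K, M)
  u <- u / sqrt(rowSums(u^2))
  mc_seed <- sample.int(.Machine$integer.max, 1L)
  vars <- matrix(1, K, M)
  overlap_at <- function(r) {
    estimate_overlap(mixture_spec(r * u, vars), n_mc = n_mc, seed = mc_seed)
  }
  lo <- 0; hi <- 1
  while (overlap_at(hi) > target_avg_overlap && hi < 1024) hi <- hi * 2
  best_r <- NA_real_; best_val <- Inf
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    val <- overlap_at(mid)
    if (abs(val - target_avg_overlap) < abs(best_val - target_avg_overlap)) {
      best_r <- mid; best_val <- val
    }
    if (abs(val / target_avg_overlap - 1) <= rel_tol) break
    if (val > target_avg_overlap) lo <- mid else hi <- mid
  }
  if (abs(best_val / target_avg_overlap - 1) > rel_tol) {
    stop(sprintf(paste0("overlap calibration failed: best %.4f vs target %.4f ",
                        "(radius %.3f) after %d iterations"),
                 best_val, target_avg_overlap, best_r, max_iter))
  }
  spec <- mixture_spec(best_r * u, vars)
  attr(spec, "achieved_overlap") <- as.numeric(best_val)
  attr(spec, "radius") <- best_r
  spec
}

new_simulated_dataset <- function(values, graph, labels, affinity, seed) {
  N <- graph$n_nodes
  expr <- expression_matrix(values, paste0("cell_", seq_len(N)),
                            graph$sample_of,
                            paste0("marker_", seq_len(ncol(values))))
  structure(list(expression = expr, graph = graph,
                 true_labels = as.integer(labels),
                 true_affinity = affinity, seed = seed),
            class = "simulated_dataset")
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf("simulated_dataset: %d cells, %d markers, K=%d\n",
              x$graph$n_nodes, ncol(x$expression$values),
              length(unique(x$true_labels))))
  invisible(x)
}

#' Forward-simulate a dataset from the spatial model
#'
#' Labels are drawn from the MRF prior (Gibbs sweeps at interaction
#' parameters sampled for the requested regime); marker expression is then
#' drawn per cell from a unit-variance Normal around its cluster's mean,
#' with cluster means drawn i.i.d. `Normal(0, emission_separation^2)` per
#' marker. Labels are always generated before expression. The default
#' separation of 1 puts cluster means about one within-cluster standard
#' deviation apart per marker on average, so a nonspatial mixture fit
#' recovers most but not all structure and spatial context has headroom to
#' contribute; the default of 500 sweeps lets the label field reach
#' equilibrium (same-label edge fractions stop drifting well before that).
#'
#' @param graph A [neighbour_graph()] (see [synthetic_spatial_graph()]).
#' @param K Number of clusters (default 8).
#' @param M Number of markers (default 10).
#' @param regime `"biased"` or `"uniform"` interaction regime.
#' @param emission_separation Standard deviation of the cluster-mean draw
#'   (default 1); larger values separate expression profiles more.
#' @param n_sweeps MRF Gibbs sweeps for the label simulation (default 500).
#' @param seed Optional integer seed.
#' @return A `simulated_dataset`: list with `expression`
#'   ([expression_matrix()]), `graph`, `true_labels`, `true_affinity` and
#'   `seed`.
#' @export
simulate_forward <- function(graph, K = 8L, M = 10L,
                             regime = c("uniform", "biased"),
                             emission_separation = 1, n_sweeps = 500L,
                             seed = NULL) {
  regime <- match.arg(regime)
  if (!is.null(seed)) set.seed(seed)
  affinity <- sample_interactions(K, regime)
  labels <- simulate_labels(graph, affinity, n_sweeps = n_sweeps)
  means <- matrix(stats::rnorm(K * M, 0, emission_separation), K, M)
  N <- graph$n_nodes
  values <- means[labels, , drop = FALSE] + matrix(stats::rnorm(N * M), N, M)
  new_simulated_dataset(values, graph, labels, affinity, seed)
}

#' Simulate a dataset with overlap-calibrated expression profiles
#'
#' As [simulate_forward()] for the label field, but marker expression is
#' drawn from a Gaussian mixture whose components are calibrated to a
#' target average pairwise overlap, so the difficulty of the expression
#' signal is controlled explicitly.
#'
#' @param graph A [neighbour_graph()].
#' @param K,M Cluster and marker counts.
#' @param target_overlap Target average pairwise component overlap.
#' @param regime `"biased"` or `"uniform"`.
#' @param n_sweeps MRF Gibbs sweeps for label simulation.
#' @param seed Optional integer seed.
#' @param ... Further arguments to [calibrate_overlap()].
#' @return A `simulated_dataset` with the calibrated [mixture_spec()]
#'   attached as attribute `"mixture_spec"`.
#' @export
simulate_overlap_study <- function(graph, K = 8L, M = 10L, target_overlap,
                                   regime = c("biased", "uniform"),
                                   n_sweeps = 500L, seed = NULL, ...) {
  regime <- match.arg(regime)
  if (!is.null(seed)) set.seed(seed)
  affinity <- sample_interactions(K, regime)
  labels <- simulate_labels(graph, affinity, n_sweeps = n_sweeps)
  spec <- calibrate_overlap(K, M, target_overlap,
                            seed = sample.int(.Machine$integer.max, 1L), ...)
  N <- graph$n_nodes
  z <- matrix(stats::rnorm(N * M), N, M)
  values <- spec$means[labels, , drop = FALSE] +
    z * sqrt(spec$variances[labels, , drop = FALSE])
  out <- new_simulated_dataset(values, graph, labels, affinity, seed)
  attr(out, "mixture_spec") <- spec
  out
}

#' Synthetic labelled expression pool
#'
#' Generates a synthetic stand-in for a gated, arcsinh-transformed mass
#' cytometry reference: a 13-marker Gaussian mixture over eight immune-like
#' populations with uneven abundances and population-specific marker
#' signatures (values roughly in 0-4, as after arcsinh with cofactor 5).
#' Used to drive semireal assembly and anchor-mode label transfer without
#' any external download; it is synthetic data, not a real reference.
#'
#' @param n_cells Pool size.
#' @param seed Optional integer seed.
#' @return List with `expression` (n_cells x 13 matrix), `labels`
#'   (integer 1..8), `population_names` and `means` (the 8 x 13 signature
#'   matrix).
#' @export
simulate_labelled_pool <- function(n_cells = 4000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pops <- c("B", "CD4_T", "CD8_T", "NK", "monocyte", "DC", "HSPC", "plasma")
  markers <- c("CD45", "CD19", "CD3", "CD4", "CD8", "CD45RO", "CD57", "CD11b",
               "CD14", "CD34", "CD38", "HLA_DR", "CD16")
  # lineage-style signature matrix: high ~3, intermediate ~1.5, low ~0.2
  sig <- matrix(0.2, length(pops), length(markers),
                dimnames = list(pops, markers))
  sig["B", c("CD45", "CD19", "HLA_DR")] <- c(3, 3, 2.5)
  sig["CD4_T", c("CD45", "CD3", "CD4", "CD45RO")] <- c(3, 3, 2.8, 1.5)
  sig["CD8_T", c("CD45", "CD3", "CD8", "CD57")] <- c(3, 3, 2.8, 1.2)
  sig["NK", c("CD45", "CD57", "CD16", "CD38")] <- c(2.8, 2.5, 2.8, 1.5)
  sig["monocyte", c("CD45", "CD11b", "CD14", "HLA_DR", "CD16")] <- c(2.8, 3, 3, 2, 1.5)
  sig["DC", c("CD45", "HLA_DR", "CD11b", "CD38")] <- c(2.5, 3, 1.5, 1.5)
  sig["HSPC", c("CD45", "CD34", "CD38")] <- c(1.5, 3, 2.5)
  sig["plasma", c("CD38", "CD19", "HLA_DR")] <- c(3.5, 1.2, 1.5)
  props <- c(0.25, 0.22, 0.15, 0.10, 0.12, 0.06, 0.04, 0.06)
  labels <- sample.int(length(pops), n_cells, replace = TRUE, prob = props)
  values <- sig[labels, , drop = FALSE] +
    matrix(stats::rnorm(n_cells * length(markers), 0, 0.45),
           n_cells, length(markers))
  dimnames(values) <- list(NULL, markers)
  list(expression = values, labels = labels, population_names = pops,
       means = sig)
}

#' Assemble a semireal dataset from a labelled pool
#'
#' Attaches real (or reference) expression profiles to a simulated spatial
#' label field: each node receives the expression row of a pool cell drawn
#' from the stratum matching its simulated label, without replacement while
#' profiles remain and with replacement (with a warning) once a stratum is
#' exhausted. The result has genuine expression variability but known
#' labels and known spatial structure.
#'
#' @param pool_expression Pool cells x markers matrix.
#' @param pool_labels Integer pool labels in 1..K.
#' @param graph A [neighbour_graph()].
#' @param simulated_labels Integer labels on the graph nodes (1..K).
#' @param seed Optional integer seed.
#' @return A `simulated_dataset`; `true_affinity` is `NULL` (the labels
#'   were supplied, not drawn here).
#' @export
assemble_semireal <- function(pool_expression, pool_labels, graph,
                              simulated_labels, seed = NULL) {
  pool_expression <- as.matrix(pool_expression)
  pool_labels <- as.integer(pool_labels)
  simulated_labels <- as.integer(simulated_labels)
  if (length(simulated_labels) != graph$n_nodes) {
    stop("simulated_labels must cover every graph node")
  }
  missing <- setdiff(unique(simulated_labels), unique(pool_labels))
  if (length(missing) > 0L) {
    stop("pool has no cells for label(s): ", paste(missing, collapse = ", "))
  }
  if (!is.null(seed)) set.seed(seed)
  N <- graph$n_nodes
  values <- matrix(NA_real_, N, ncol(pool_expression))
  for (k in unique(simulated_labels)) {
    nodes <- which(simulated_labels == k)
    stratum <- which(pool_labels == k)
    if (length(nodes) <= length(stratum)) {
      pick <- sample(stratum, length(nodes))
    } else {
      warning(sprintf("pool stratum %d exhausted (%d cells for %d nodes); ",
                      k, length(stratum), length(nodes)),
              "continuing with replacement")
      pick <- c(sample(stratum, length(stratum)),
                sample(stratum, length(nodes) - length(stratum), replace = TRUE))
    }
    values[nodes, ] <- pool_expression[pick, , drop = FALSE]
  }
  out <- new_simulated_dataset(values, graph, simulated_labels, NULL, seed)
  if (!is.null(colnames(pool_expression))) {
    out$expression$marker_names <- colnames(pool_expression)
    colnames(out$expression$values) <- colnames(pool_expression)
  }
  out
}

#' Write a simulated dataset to CSV files
#'
#' Writes `<stem>_expression.csv`, `<stem>_truth.csv`, and (when the graph
#' carries locations) `<stem>_locations.csv`, plus `<stem>_edges.csv`.
#'
#' @param dataset A `simulated_dataset`.
#' @param stem Output path stem.
#' @return The written paths, invisibly.
#' @export
write_dataset_csv <- function(dataset, stem) {
  expr <- dataset$expression
  paths <- character(0)
  p <- paste0(stem, "_expression.csv")
  write_expression_csv(expr, p); paths <- c(paths, p)
  p <- paste0(stem, "_truth.csv")
  write_labels_csv(dataset$true_labels, expr, p); paths <- c(paths, p)
  loc <- attr(dataset$graph, "locations")
  if (!is.null(loc)) {
    p <- paste0(stem, "_locations.csv")
    utils::write.csv(loc, p, row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  e <- dataset$graph$edges
  p <- paste0(stem, "_edges.csv")
  utils::write.csv(data.frame(cell_id_a = expr$cell_ids[e[, 1L]],
                              cell_id_b = expr$cell_ids[e[, 2L]],
                              sample_id = expr$sample_ids[e[, 1L]]),
                   p, row.names = FALSE, quote = FALSE)
  paths <- c(paths, p)
  invisible(paths)
}
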