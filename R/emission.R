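#' Normal-Gamma hyperparameters
#'
#' Conjugate prior for the (mean, precision) of a Normal emission:
#' `tau ~ Gamma(alpha0, b0)`, `mu | tau ~ Normal(mu0, 1/(lambda0 tau))`.
#' The Gamma rate is called `b0` here to keep it distinct from the MRF
#' affinity matrix.
#'
#' @param mu0 Prior mean.
#' @param lambda0 Positive prior mean-precision scale.
#' @param alpha0 Positive Gamma shape.
#' @param b0 Positive Gamma rate.
#' @return An object of class `normal_gamma`.
#' @export
normal_gamma <- function(mu0 = 0, lambda0 = 1, alpha0 = 1, b0 = 1) {
  if (lambda0 <= 0 || alpha0 <= 0 || b0 <= 0) {
    stop("lambda0, alpha0 and b0 must be positive")
  }
  structure(list(mu0 = mu0, lambda0 = lambda0, alpha0 = alpha0, b0 = b0),
            class = "normal_gamma")
}

#' Empty sufficient statistics
#'
#' Running count, sum and sum of squares of the observations currently
#' assigned to one (cluster, marker) cell.
#'
#' @return An object of class `suff_stats` with `n = 0`.
#' @export
suff_stats <- function() {
  structure(list(n = 0L, sum = 0, sumsq = 0), class = "suff_stats")
}

#' Add or remove an observation from sufficient statistics
#'
#' @param stats A [suff_stats()] object.
#' @param y Scalar observation.
#' @param direction `"add"` or `"remove"`.
#' @return Updated `suff_stats`.
#' @export
update_stats <- function(stats, y, direction = c("add", "remove")) {
  direction <- match.arg(direction)
  if (direction == "add") {
    stats$n <- stats$n + 1L
    stats$sum <- stats$sum + y
    stats$sumsq <- stats$sumsq + y * y
  } else {
    if (stats$n < 1L) stop("cannot remove an observation from empty statistics")
    stats$n <- stats$n - 1L
    stats$sum <- stats$sum - y
    stats$sumsq <- stats$sumsq - y * y
    if (stats$n == 0L) { stats$sum <- 0; stats$sumsq <- 0 }
  }
  stats
}

#' Batch sufficient statistics of a numeric vector
#'
#' @param values Numeric vector.
#' @return A [suff_stats()] object.
#' @export
stats_from_values <- function(values) {
  s <- suff_stats()
  s$n <- length(values)
  s$sum <- sum(values)
  s$sumsq <- sum(values^2)
  s
}

#' Normal-Gamma posterior parameters given sufficient statistics
#'
#' Standard conjugate update for n observations with mean `ybar` and
#' centred sum of squares `ss = sumsq - sum^2/n`:
#' `mu_n = (lambda0 mu0 + n ybar) / (lambda0 + n)`, `lambda_n = lambda0 + n`,
#' `alpha_n = alpha0 + n/2`,
#' `b_n = b0 + ss/2 + lambda0 n (ybar - mu0)^2 / (2 (lambda0 + n))`.
#'
#' @param prior A [normal_gamma()] prior.
#' @param stats A [suff_stats()] object.
#' @return A [normal_gamma()] holding the posterior parameters.
#' @export
posterior_params <- function(prior, stats) {
  n <- stats$n
  if (n == 0L) return(prior)
  ybar <- stats$sum / n
  ss <- max(stats$sumsq - stats$sum^2 / n, 0)
  lambda_n <- prior$lambda0 + n
  normal_gamma(
    mu0 = (prior$lambda0 * prior$mu0 + stats$sum) / lambda_n,
    lambda0 = lambda_n,
    alpha0 = prior$alpha0 + n / 2,
    b0 = prior$b0 + ss / 2 +
      prior$lambda0 * n * (ybar - prior$mu0)^2 / (2 * lambda_n)
  )
}

#' Log posterior-predictive density under a Normal-Gamma
#'
#' Integrating the Normal emission over its Normal-Gamma law gives a
#' Student-t density with `nu = 2 alpha` degrees of freedom, location `mu`
#' and squared scale `b (lambda + 1) / (alpha lambda)`.
#'
#' @param y Numeric vector of points at which to evaluate.
#' @param params A [normal_gamma()] (prior or posterior).
#' @return Log density values, same length as `y`.
#' @export
log_predictive <- function(y, params) {
  nu <- 2 * params$alpha0
  s2 <- params$b0 * (params$lambda0 + 1) / (params$alpha0 * params$lambda0)
  z <- (y - params$mu0) / sqrt(s2)
  stats::dt(z, df = nu, log = TRUE) - 0.5 * log(s2)
}

#' Emission hyperparameter grid
#'
#' Per-(cluster, marker) Normal-Gamma hyperparameters plus fixed anchor
#' contributions, in the layout used by the samplers. Scalars are recycled
#' across the K x M grid.
#'
#' @param K,M Cluster and marker counts.
#' @param mu0,lambda0,alpha0,b0 Scalars or K x M matrices.
#' @return An object of class `emission_hyper` with K x M matrices `mu0`,
#'   `lambda0`, `alpha0`, `b0` and zeroed anchor statistics (`anchor_n`,
#'   `anchor_sum`, `anchor_sumsq`).
#' @export
emission_hyper <- function(K, M, mu0 = 0, lambda0 = 1, alpha0 = 1, b0 = 1) {
  expand <- function(v, name) {
    if (length(v) == 1L) return(matrix(v, K, M))
    v <- as.matrix(v)
    if (!all(dim(v) == c(K, M))) stop(name, " must be scalar or a K x M matrix")
    v
  }
  lambda0 <- expand(lambda0, "lambda0"); alpha0 <- expand(alpha0, "alpha0")
  b0 <- expand(b0, "b0")
  if (any(lambda0 <= 0) || any(alpha0 <= 0) || any(b0 <= 0)) {
    stop("lambda0, alpha0 and b0 must be positive")
  }
  structure(list(K = as.integer(K), M = as.integer(M),
                 mu0 = expand(mu0, "mu0"), lambda0 = lambda0,
                 alpha0 = alpha0, b0 = b0,
                 anchor_n = numeric(K),
                 anchor_sum = matrix(0, K, M),
                 anchor_sumsq = matrix(0, K, M),
                 cluster_names = NULL),
            class = "emission_hyper")
}

#' Encode a quaternary prior expression matrix into emission priors
#'
#' Prior knowledge of expected marker levels per cell population is given
#' as a K x M matrix with codes in \{-1, 0, 1, 2\}. Codes 0, 1 and 2 map the
#' prior mean `mu0` of that (cluster, marker) cell to the 25th, 50th and
#' 75th percentile of the marker's expression over all cells, with an
#' informative mean-precision scale; code -1 means no prior knowledge and
#' maps to mean zero with a vague (small) scale, i.e. high prior variance
#' on the mean.
#'
#' @param codes Integer K x M matrix with entries in \{-1, 0, 1, 2\};
#'   columns must follow the marker order of `expr`. Row names, if present,
#'   become cluster names.
#' @param expr The query [expression_matrix()].
#' @param lambda_informative Mean-precision scale for codes 0/1/2.
#' @param lambda_vague Mean-precision scale for code -1.
#' @param alpha0,b0 Gamma shape and rate shared by all cells of the grid.
#' @return An [emission_hyper()] grid.
#' @export
encode_prior_matrix <- function(codes, expr, lambda_informative = 1,
                                lambda_vague = 0.01, alpha0 = 1, b0 = 1) {
  codes_m <- as.matrix(codes)
  if (!all(codes_m %in% c(-1, 0, 1, 2))) {
    stop("prior expression codes must be in {-1, 0, 1, 2}")
  }
  if (ncol(codes_m) != ncol(expr$values)) {
    stop("prior matrix must have one column per marker")
  }
  K <- nrow(codes_m); M <- ncol(codes_m)
  q <- apply(expr$values, 2L, stats::quantile,
             probs = c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  mu0 <- matrix(0, K, M)
  lambda0 <- matrix(lambda_vague, K, M)
  for (k in seq_len(K)) {
    for (m in seq_len(M)) {
      code <- codes_m[k, m]
      if (code >= 0) {
        mu0[k, m] <- q[code + 1L, m]
        lambda0[k, m] <- lambda_informative
      }
    }
  }
  out <- emission_hyper(K, M, mu0 = mu0, lambda0 = lambda0,
                        alpha0 = alpha0, b0 = b0)
  out$cluster_names <- rownames(codes_m)
  out
}

#' Read a prior expression matrix from CSV
#'
#' First column holds cluster names; remaining columns are markers with
#' codes in \{-1, 0, 1, 2\}.
#'
#' @param path CSV path.
#' @param expr The companion [expression_matrix()]; columns are aligned to
#'   its marker order.
#' @return Integer matrix with cluster row names, marker column names.
#' @export
read_prior_matrix_csv <- function(path, expr) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  clusters <- as.character(df[[1L]])
  codes <- as.matrix(df[, -1L, drop = FALSE])
  missing <- setdiff(expr$marker_names, colnames(codes))
  if (length(missing) > 0L) {
    stop("prior matrix missing markers: ", paste(missing, collapse = ", "))
  }
  codes <- codes[, expr$marker_names, drop = FALSE]
  storage.mode(codes) <- "integer"
  rownames(codes) <- clusters
  codes
}

#' Build an anchor set
#'
#' Anchors are externally labelled expression profiles (for example gated
#' cells from a disaggregated assay) with fixed, never-resampled cluster
#' assignments. They pin each labelled cluster to an expression signature
#' by contributing permanently to its sufficient statistics, but they take
#' no part in the spatial neighbour graph. Clusters without anchors remain
#' free to be discovered.
#'
#' @param expression A x M numeric matrix of anchor profiles, columns in
#'   the query's marker order (columns are matched by name when both are
#'   named).
#' @param labels Length-A integer (or factor/character) cluster labels.
#' @param K Number of clusters.
#' @return An object of class `anchor_set` with fields `expression`,
#'   `labels` (integer) and `cluster_names`.
#' @export
anchor_set <- function(expression, labels, K) {
  expression <- as.matrix(expression)
  cluster_names <- NULL
  if (is.factor(labels) || is.character(labels)) {
    f <- factor(labels)
    cluster_names <- levels(f)
    labels <- as.integer(f)
  }
  labels <- as.integer(labels)
  if (length(labels) != nrow(expression)) stop("one label per anchor row required")
  if (length(labels) > 0L && (any(labels < 1L) || any(labels > K))) {
    stop("anchor labels must lie in 1..K")
  }
  structure(list(expression = expression, labels = labels, K = as.integer(K),
                 cluster_names = cluster_names),
            class = "anchor_set")
}

#' Read anchors from CSV
#'
#' @param path CSV with marker columns plus a `label` column.
#' @param expr The companion [expression_matrix()]; anchor columns are
#'   aligned to its marker order.
#' @param K Number of clusters.
#' @return An [anchor_set()].
#' @export
read_anchors_csv <- function(path, expr, K) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"label" %in% names(df)) stop("anchors CSV must contain a 'label' column")
  missing <- setdiff(expr$marker_names, names(df))
  if (length(missing) > 0L) {
    stop("anchors CSV missing markers: ", paste(missing, collapse = ", "))
  }
  anchor_set(as.matrix(df[, expr$marker_names, drop = FALSE]), df$label, K)
}

#' Register anchors into an emission hyperparameter grid
#'
#' Adds each anchor's expression to the permanent sufficient statistics of
#' its cluster. Warns when the anchor and query expression scales look
#' grossly mismatched (ratio of median absolute deviations above 5),
#' since anchors are expected to be pre-transformed to the query scale.
#'
#' @param hyper An [emission_hyper()] grid.
#' @param anchors An [anchor_set()].
#' @param expr Optional query [expression_matrix()] used for the scale
#'   check.
#' @return The updated `emission_hyper`.
#' @export
register_anchors <- function(hyper, anchors, expr = NULL) {
  stopifnot(inherits(hyper, "emission_hyper"), inherits(anchors, "anchor_set"))
  if (nrow(anchors$expression) == 0L) return(hyper)
  if (ncol(anchors$expression) != hyper$M) {
    stop("anchor expression must have one column per marker")
  }
  if (any(anchors$labels > hyper$K)) stop("anchor label exceeds K")
  if (!is.null(expr)) {
    mad_q <- stats::mad(expr$values)
    mad_a <- stats::mad(anchors$expression)
    if (mad_q > 0 && mad_a > 0) {
      ratio <- max(mad_q / mad_a, mad_a / mad_q)
      if (ratio > 5) {
        warning("anchor and query expression scales differ by more than 5x; ",
                "anchors should be transformed to the query scale")
      }
    }
  }
  for (k in unique(anchors$labels)) {
    rows <- anchors$expression[anchors$labels == k, , drop = FALSE]
    hyper$anchor_n[k] <- hyper$anchor_n[k] + nrow(rows)
    hyper$anchor_sum[k, ] <- hyper$anchor_sum[k, ] + colSums(rows)
    hyper$anchor_sumsq[k, ] <- hyper$anchor_sumsq[k, ] + colSums(rows^2)
  }
  if (is.null(hyper$cluster_names)) hyper$cluster_names <- anchors$cluster_names
  hyper
}

#' Log marginal likelihood of a sample under a Normal-Gamma prior
#'
#' Closed form for the evidence of `n` Normal observations with the
#' emission parameters integrated out; used by exact-enumeration oracles
#' for the collapsed sampler.
#'
#' @param values Numeric vector of observations.
#' @param prior A [normal_gamma()] prior.
#' @return Log marginal likelihood (0 for an empty vector).
#' @export
log_marginal_likelihood <- function(values, prior) {
  n <- length(values)
  if (n == 0L) return(0)
  post <- posterior_params(prior, stats_from_values(values))
  lgamma(post$alpha0) - lgamma(prior$alpha0) +
    prior$alpha0 * log(prior$b0) - post$alpha0 * log(post$b0) +
    0.5 * (log(prior$lambda0) - log(post$lambda0)) -
    (n / 2) * log(2 * pi)
}
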