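#' Posterior similarity matrix of a trace
#'
#' Entry (i, j) is the fraction of retained (post-burn-in) samples in which
#' cells i and j are assigned to the same cluster.
#'
#' @param trace An `hmrf_trace`, or an S x N integer matrix of label
#'   samples.
#' @param burn_in_fraction Fraction of the trace discarded from the front;
#'   defaults to the trace's own setting (0.5).
#' @return N x N symmetric numeric matrix with unit diagonal, class
#'   `psm`.
#' @export
posterior_similarity <- function(trace, burn_in_fraction = NULL) {
  samples <- retained_samples(trace, burn_in_fraction)
  structure(cpp_psm(samples), class = c("psm", "matrix"))
}

retained_samples <- function(trace, burn_in_fraction = NULL) {
  if (inherits(trace, "hmrf_trace")) {
    if (is.null(burn_in_fraction)) burn_in_fraction <- trace$burn_in_fraction
    samples <- trace$labels
  } else {
    if (is.null(burn_in_fraction)) burn_in_fraction <- 0
    samples <- as.matrix(trace)
  }
  storage.mode(samples) <- "integer"
  drop_n <- floor(nrow(samples) * burn_in_fraction)
  if (drop_n >= nrow(samples)) stop("burn-in leaves no retained samples")
  samples[(drop_n + 1L):nrow(samples), , drop = FALSE]
}

#' Posterior expected adjusted Rand of a partition against a PSM
#'
#' Scores a candidate partition against the posterior similarity matrix by
#' the expected adjusted Rand index under the posterior over partitions:
#' with I_ij the same-cluster indicator of the candidate, p_ij the PSM
#' entries and C = N(N-1)/2 pairs,
#' `PEAR = (sum I p - sum I sum p / C) / ((sum I + sum p)/2 - sum I sum p / C)`
#' where all sums run over unordered pairs i < j. A degenerate denominator
#' (zero) returns 0 by convention.
#'
#' @param partition Integer label vector.
#' @param psm A [posterior_similarity()] matrix.
#' @return The PEAR score.
#' @export
pear_score <- function(partition, psm) {
  N <- length(partition)
  if (N != nrow(psm)) stop("partition and PSM sizes differ")
  C <- N * (N - 1) / 2
  sum_p <- (sum(psm) - N) / 2
  sum_i <- 0
  sum_ip <- 0
  for (k in unique(partition)) {
    idx <- which(partition == k)
    nk <- length(idx)
    if (nk < 2L) next
    sum_i <- sum_i + nk * (nk - 1) / 2
    sum_ip <- sum_ip + (sum(psm[idx, idx]) - nk) / 2
  }
  expected <- sum_i * sum_p / C
  denom <- (sum_i + sum_p) / 2 - expected
  if (abs(denom) < .Machine$double.eps^0.5) return(0)
  (sum_ip - expected) / denom
}

#' Consensus partition by maximum posterior expected adjusted Rand
#'
#' Cluster labels are unidentifiable in unsupervised mode (the posterior is
#' invariant to label permutation), so the trace is summarized through the
#' label-invariant posterior similarity matrix: among a candidate set
#' consisting of every retained sampled partition plus average-linkage cuts
#' of `1 - PSM` into 2..K clusters, the partition maximizing [pear_score()]
#' is returned. Ties break toward the earliest candidate.
#'
#' @param trace An `hmrf_trace` (or S x N label matrix).
#' @param psm Optional precomputed [posterior_similarity()] matrix.
#' @param burn_in_fraction Passed to [posterior_similarity()].
#' @param max_k Largest hierarchical cut to try (defaults to the trace's K,
#'   or the largest sampled label).
#' @return Integer label vector (the consensus partition), with the
#'   winning score attached as attribute `"pear"`.
#' @export
mpear_point_estimate <- function(trace, psm = NULL, burn_in_fraction = NULL,
                                 max_k = NULL) {
  samples <- retained_samples(trace, burn_in_fraction)
  if (is.null(psm)) {
    psm <- structure(cpp_psm(samples), class = c("psm", "matrix"))
  }
  if (is.null(max_k)) {
    max_k <- if (inherits(trace, "hmrf_trace")) trace$K else max(samples)
  }
  candidates <- lapply(seq_len(nrow(samples)), function(s) samples[s, ])
  candidates <- candidates[!duplicated(samples)]
  if (nrow(psm) > 1L && max_k >= 2L) {
    hc <- stats::hclust(stats::as.dist(1 - unclass(psm)), method = "average")
    for (k in 2:max_k) candidates <- c(candidates, list(stats::cutree(hc, k)))
  }
  scores <- vapply(candidates, pear_score, numeric(1L), psm = psm)
  best <- which.max(scores)  # which.max takes the earliest maximum
  structure(as.integer(candidates[[best]]), pear = scores[best])
}

#' Last retained sample of a trace
#'
#' In prior and anchor mode the clusters are identifiable (each is pinned
#' to a signature), so the final sampled labelling is used as the point
#' estimate. Cluster names from the prior matrix or anchor set are carried
#' along when present.
#'
#' @param trace An `hmrf_trace`.
#' @return Integer label vector; named-cluster mapping (if any) attached as
#'   attribute `"cluster_names"`.
#' @export
last_sample_estimate <- function(trace) {
  samples <- retained_samples(trace)
  out <- samples[nrow(samples), ]
  attr(out, "cluster_names") <- if (inherits(trace, "hmrf_trace")) trace$cluster_names
  out
}
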