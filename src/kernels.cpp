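#include <Rcpp.h>
using namespace Rcpp;

// Sampling kernels for the hidden Markov random field model. All random
// draws go through R's RNG (unif_rand) so results are reproducible from
// set.seed() on the R side. Labels are 1-based throughout, matching R.

namespace {

// draw an index in [0, K) from unnormalized log-weights (log-sum-exp)
inline int sample_log_weights(const std::vector<double>& logw) {
  const int K = (int) logw.size();
  double mx = logw[0];
  for (int k = 1; k < K; ++k) if (logw[k] > mx) mx = logw[k];
  double tot = 0.0;
  std::vector<double> w(K);
  for (int k = 0; k < K; ++k) { w[k] = std::exp(logw[k] - mx); tot += w[k]; }
  double u = unif_rand() * tot, acc = 0.0;
  for (int k = 0; k < K; ++k) { acc += w[k]; if (u <= acc) return k; }
  return K - 1;  // numerical guard
}

}  // namespace

// One or more Gibbs sweeps over a label field under the MRF prior alone:
// p(x_n = k | x_{N(n)}) is proportional to exp(sum_{n' in N(n)} beta[k, x_{n'}]).
// Systematic scan in ascending node index unless random_scan is set.
// [[Rcpp::export]]
IntegerVector cpp_potts_sweeps(IntegerVector labels, List adj,
                               NumericMatrix beta, int n_sweeps,
                               bool random_scan) {
  const int N = labels.size();
  const int K = beta.nrow();
  IntegerVector x = clone(labels);
  std::vector<double> logw(K);
  for (int s = 0; s < n_sweeps; ++s) {
    for (int i = 0; i < N; ++i) {
      int n = i;
      if (random_scan) n = (int) std::floor(unif_rand() * N) % N;
      IntegerVector nb = adj[n];
      for (int k = 0; k < K; ++k) {
        double e = 0.0;
        for (int j = 0; j < nb.size(); ++j) e += beta(k, x[nb[j] - 1] - 1);
        logw[k] = e;
      }
      x[n] = sample_log_weights(logw) + 1;
    }
  }
  return x;
}

// Sum of beta[x_u, x_v] over unordered edges (log of the unnormalized MRF weight).
// [[Rcpp::export]]
double cpp_log_potential(IntegerMatrix edges, IntegerVector labels,
                         NumericMatrix beta) {
  double tot = 0.0;
  for (int e = 0; e < edges.nrow(); ++e) {
    tot += beta(labels[edges(e, 0) - 1] - 1, labels[edges(e, 1) - 1] - 1);
  }
  return tot;
}

// One systematic collapsed-Gibbs sweep over non-anchored cells. Emission
// parameters are integrated out under per-(cluster, marker) Normal-Gamma
// priors, so each candidate cluster is scored by its Student-t posterior
// predictive plus the MRF neighbour term. Sufficient statistics (counts,
// sums, sums of squares, including fixed anchor contributions) are
// maintained incrementally inside the sweep: each cell is removed from its
// cluster before rescoring and re-added after assignment.
// [[Rcpp::export]]
IntegerVector cpp_collapsed_sweep(IntegerVector labels, List adj,
                                  NumericMatrix beta, NumericMatrix Y,
                                  NumericVector anchor_n,
                                  NumericMatrix anchor_sum,
                                  NumericMatrix anchor_sumsq,
                                  NumericMatrix mu0, NumericMatrix lambda0,
                                  NumericMatrix alpha0, NumericMatrix b0,
                                  LogicalVector fixed) {
  const int N = Y.nrow(), M = Y.ncol(), K = beta.nrow();
  IntegerVector x = clone(labels);

  // stats from current labels plus anchors
  std::vector<double> cnt(K, 0.0);
  NumericMatrix sum_(K, M), sumsq(K, M);
  for (int k = 0; k < K; ++k) {
    cnt[k] = anchor_n[k];
    for (int m = 0; m < M; ++m) { sum_(k, m) = anchor_sum(k, m); sumsq(k, m) = anchor_sumsq(k, m); }
  }
  for (int n = 0; n < N; ++n) {
    int k = x[n] - 1;
    cnt[k] += 1.0;
    for (int m = 0; m < M; ++m) { sum_(k, m) += Y(n, m); sumsq(k, m) += Y(n, m) * Y(n, m); }
  }

  // lgamma terms depend on alpha_n = alpha0 + n_k/2 only; when alpha0 is
  // constant within a cluster row (the usual case) they can be computed
  // once per cluster instead of once per marker
  bool alpha_row_const = true;
  for (int k = 0; k < K && alpha_row_const; ++k) {
    for (int m = 1; m < M; ++m) {
      if (alpha0(k, m) != alpha0(k, 0)) { alpha_row_const = false; break; }
    }
  }

  std::vector<double> logw(K);
  for (int n = 0; n < N; ++n) {
    if (fixed[n]) continue;
    int kc = x[n] - 1;
    cnt[kc] -= 1.0;
    for (int m = 0; m < M; ++m) { sum_(kc, m) -= Y(n, m); sumsq(kc, m) -= Y(n, m) * Y(n, m); }

    IntegerVector nb = adj[n];
    for (int k = 0; k < K; ++k) {
      double lp = 0.0;
      for (int j = 0; j < nb.size(); ++j) lp += beta(k, x[nb[j] - 1] - 1);
      double nk = cnt[k];
      double lg_cache = 0.0;
      if (alpha_row_const) {
        double ak = alpha0(k, 0) + 0.5 * nk;
        lg_cache = R::lgammafn(ak + 0.5) - R::lgammafn(ak);
      }
      for (int m = 0; m < M; ++m) {
        double l0 = lambda0(k, m), m0 = mu0(k, m);
        double ln = l0 + nk, an = alpha0(k, m) + 0.5 * nk, bn = b0(k, m);
        double mun = m0;
        if (nk > 0.0) {
          double ybar = sum_(k, m) / nk;
          mun = (l0 * m0 + sum_(k, m)) / ln;
          double ss = sumsq(k, m) - nk * ybar * ybar;
          if (ss < 0.0) ss = 0.0;  // rounding guard
          double dev = ybar - m0;
          bn += 0.5 * ss + l0 * nk * dev * dev / (2.0 * ln);
        }
        // Student-t posterior predictive: nu = 2 an, scale^2 = bn (ln+1)/(an ln)
        double nu = 2.0 * an;
        double s2 = bn * (ln + 1.0) / (an * ln);
        double z = Y(n, m) - mun;
        double lg = alpha_row_const ? lg_cache
                                    : R::lgammafn(an + 0.5) - R::lgammafn(an);
        lp += lg - 0.5 * std::log(nu * M_PI * s2)
            - (an + 0.5) * std::log1p(z * z / (nu * s2));
      }
      logw[k] = lp;
    }
    int knew = sample_log_weights(logw);
    x[n] = knew + 1;
    cnt[knew] += 1.0;
    for (int m = 0; m < M; ++m) { sum_(knew, m) += Y(n, m); sumsq(knew, m) += Y(n, m) * Y(n, m); }
  }
  return x;
}

// Posterior similarity matrix: entry (i, j) is the fraction of samples
// (rows of label_samples) in which cells i and j share a label.
// [[Rcpp::export]]
NumericMatrix cpp_psm(IntegerMatrix label_samples) {
  const int S = label_samples.nrow(), N = label_samples.ncol();
  NumericMatrix psm(N, N);
  for (int s = 0; s < S; ++s) {
    for (int i = 0; i < N; ++i) {
      int li = label_samples(s, i);
      for (int j = i + 1; j < N; ++j) {
        if (label_samples(s, j) == li) psm(i, j) += 1.0;
      }
    }
  }
  for (int i = 0; i < N; ++i) {
    psm(i, i) = 1.0;
    for (int j = i + 1; j < N; ++j) {
      psm(i, j) /= S;
      psm(j, i) = psm(i, j);
    }
  }
  return psm;
}

// Thresholded-distance edges within each sample: {u, v} iff same sample and
// Euclidean distance strictly below threshold. Returns a 2-column matrix of
// 1-based node indices with u < v.
// [[Rcpp::export]]
IntegerMatrix cpp_threshold_edges(NumericVector x, NumericVector y,
                                  IntegerVector sample, double threshold) {
  const int N = x.size();
  const double t2 = threshold * threshold;
  std::vector<int> us, vs;
  for (int i = 0; i < N; ++i) {
    for (int j = i + 1; j < N; ++j) {
      if (sample[i] != sample[j]) continue;
      double dx = x[i] - x[j], dy = y[i] - y[j];
      if (dx * dx + dy * dy < t2) { us.push_back(i + 1); vs.push_back(j + 1); }
    }
  }
  IntegerMatrix edges((int) us.size(), 2);
  for (int e = 0; e < (int) us.size(); ++e) { edges(e, 0) = us[e]; edges(e, 1) = vs[e]; }
  return edges;
}
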