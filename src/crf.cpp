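#include <Rcpp.h>
using namespace Rcpp;

// Linear-chain CRF exact inference in log space.
// E: N x L per-position emission log-scores.
// W: L x L transition log-scores, W(i, j) = score of label i -> label j.

static double log_sum_exp(const std::vector<double>& v) {
  double m = v[0];
  for (size_t i = 1; i < v.size(); ++i) if (v[i] > m) m = v[i];
  if (!std::isfinite(m)) return m;
  double s = 0.0;
  for (size_t i = 0; i < v.size(); ++i) s += std::exp(v[i] - m);
  return m + std::log(s);
}

// [[Rcpp::export]]
double crf_log_partition_cpp(NumericMatrix E, NumericMatrix W) {
  int N = E.nrow(), L = E.ncol();
  if (N < 1) stop("empty sequence");
  std::vector<double> alpha(L), nxt(L), tmp(L);
  for (int j = 0; j < L; ++j) alpha[j] = E(0, j);
  for (int t = 1; t < N; ++t) {
    for (int j = 0; j < L; ++j) {
      for (int i = 0; i < L; ++i) tmp[i] = alpha[i] + W(i, j);
      nxt[j] = log_sum_exp(tmp) + E(t, j);
    }
    alpha = nxt;
  }
  return log_sum_exp(alpha);
}

// Forward-backward: returns logZ, node posteriors (N x L) and expected
// transition counts (L x L, summed over positions).
// [[Rcpp::export]]
List crf_marginals_cpp(NumericMatrix E, NumericMatrix W) {
  int N = E.nrow(), L = E.ncol();
  if (N < 1) stop("empty sequence");
  NumericMatrix alpha(N, L), beta(N, L), node(N, L), trans(L, L);
  std::vector<double> tmp(L);
  for (int j = 0; j < L; ++j) alpha(0, j) = E(0, j);
  for (int t = 1; t < N; ++t)
    for (int j = 0; j < L; ++j) {
      for (int i = 0; i < L; ++i) tmp[i] = alpha(t - 1, i) + W(i, j);
      alpha(t, j) = log_sum_exp(tmp) + E(t, j);
    }
  for (int j = 0; j < L; ++j) { tmp[j] = alpha(N - 1, j); beta(N - 1, j) = 0.0; }
  double logZ = log_sum_exp(tmp);
  for (int t = N - 2; t >= 0; --t)
    for (int i = 0; i < L; ++i) {
      for (int j = 0; j < L; ++j) tmp[j] = W(i, j) + E(t + 1, j) + beta(t + 1, j);
      beta(t, i) = log_sum_exp(tmp);
    }
  for (int t = 0; t < N; ++t)
    for (int j = 0; j < L; ++j)
      node(t, j) = std::exp(alpha(t, j) + beta(t, j) - logZ);
  for (int t = 1; t < N; ++t)
    for (int i = 0; i < L; ++i)
      for (int j = 0; j < L; ++j)
        trans(i, j) += std::exp(alpha(t - 1, i) + W(i, j) + E(t, j) +
                                beta(t, j) - logZ);
  return List::create(_["logZ"] = logZ, _["node"] = node, _["trans"] = trans);
}

// Viterbi decoding. Ties are broken toward the lexicographically smallest
// label-index sequence: suffix-optimal scores are computed right-to-left,
// then the path is built greedily left-to-right taking the smallest label
// index that attains the optimum at each step.
// [[Rcpp::export]]
List crf_viterbi_cpp(NumericMatrix E, NumericMatrix W) {
  int N = E.nrow(), L = E.ncol();
  if (N < 1) stop("empty sequence");
  // best(t, j): best score of the suffix t..N-1 given label j at t
  NumericMatrix best(N, L);
  for (int j = 0; j < L; ++j) best(N - 1, j) = E(N - 1, j);
  for (int t = N - 2; t >= 0; --t)
    for (int j = 0; j < L; ++j) {
      double m = R_NegInf;
      for (int k = 0; k < L; ++k) {
        double s = W(j, k) + best(t + 1, k);
        if (s > m) m = s;
      }
      best(t, j) = E(t, j) + m;
    }
  IntegerVector path(N);
  double total = R_NegInf;
  int cur = 0;
  for (int j = 0; j < L; ++j)
    if (best(0, j) > total) { total = best(0, j); cur = j; }
  path[0] = cur + 1;
  for (int t = 1; t < N; ++t) {
    double m = R_NegInf;
    int arg = 0;
    for (int k = 0; k < L; ++k) {
      double s = W(cur, k) + best(t, k);
      if (s > m) { m = s; arg = k; }
    }
    cur = arg;
    path[t] = cur + 1;
  }
  return List::create(_["path"] = path, _["score"] = total);
}
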