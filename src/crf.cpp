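#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Linear-chain CRF inference over concatenated sequences.
// emit:   n_total x K matrix of emission scores (x' w per tag)
// starts: 1-based start index of each sequence in emit
// lens:   length of each sequence
// trans:  K x K transition scores (from row to column)
// init:   K initial-state scores
//
// All recursions are in log space with a log-sum-exp over K states.

static inline double logsumexp(const std::vector<double>& v) {
  double m = v[0];
  for (size_t i = 1; i < v.size(); ++i) if (v[i] > m) m = v[i];
  double s = 0.0;
  for (size_t i = 0; i < v.size(); ++i) s += std::exp(v[i] - m);
  return m + std::log(s);
}

// [[Rcpp::export]]
List crf_forward_backward(NumericMatrix emit, IntegerVector starts,
                          IntegerVector lens, NumericMatrix trans,
                          NumericVector init) {
  const int K = emit.ncol();
  const int S = starts.size();
  const int n = emit.nrow();
  NumericMatrix marg(n, K);        // node marginals P(y_t = k)
  NumericMatrix etrans(K, K);      // expected transition counts
  NumericVector einit(K);          // expected initial counts
  double logZ_total = 0.0;

  for (int s = 0; s < S; ++s) {
    const int off = starts[s] - 1;
    const int T = lens[s];
    if (T == 0) continue;
    std::vector<double> alpha(T * K), beta(T * K), tmp(K);
    for (int k = 0; k < K; ++k) alpha[k] = init[k] + emit(off, k);
    for (int t = 1; t < T; ++t) {
      for (int k = 0; k < K; ++k) {
        for (int j = 0; j < K; ++j)
          tmp[j] = alpha[(t - 1) * K + j] + trans(j, k);
        alpha[t * K + k] = logsumexp(tmp) + emit(off + t, k);
      }
    }
    for (int k = 0; k < K; ++k) tmp[k] = alpha[(T - 1) * K + k];
    const double logZ = logsumexp(tmp);
    logZ_total += logZ;

    for (int k = 0; k < K; ++k) beta[(T - 1) * K + k] = 0.0;
    for (int t = T - 2; t >= 0; --t) {
      for (int k = 0; k < K; ++k) {
        for (int j = 0; j < K; ++j)
          tmp[j] = trans(k, j) + emit(off + t + 1, j) + beta[(t + 1) * K + j];
        beta[t * K + k] = logsumexp(tmp);
      }
    }
    for (int t = 0; t < T; ++t)
      for (int k = 0; k < K; ++k)
        marg(off + t, k) = std::exp(alpha[t * K + k] + beta[t * K + k] - logZ);
    for (int k = 0; k < K; ++k) einit[k] += marg(off, k);
    for (int t = 1; t < T; ++t)
      for (int j = 0; j < K; ++j)
        for (int k = 0; k < K; ++k)
          etrans(j, k) += std::exp(alpha[(t - 1) * K + j] + trans(j, k) +
                                   emit(off + t, k) + beta[t * K + k] - logZ);
  }
  return List::create(_["logZ"] = logZ_total, _["marginals"] = marg,
                      _["etrans"] = etrans, _["einit"] = einit);
}

// [[Rcpp::export]]
IntegerVector crf_viterbi(NumericMatrix emit, IntegerVector starts,
                          IntegerVector lens, NumericMatrix trans,
                          NumericVector init) {
  const int K = emit.ncol();
  const int S = starts.size();
  IntegerVector path(emit.nrow());

  for (int s = 0; s < S; ++s) {
    const int off = starts[s] - 1;
    const int T = lens[s];
    if (T == 0) continue;
    std::vector<double> delta(T * K);
    std::vector<int> psi(T * K);
    for (int k = 0; k < K; ++k) delta[k] = init[k] + emit(off, k);
    for (int t = 1; t < T; ++t) {
      for (int k = 0; k < K; ++k) {
        double best = delta[(t - 1) * K] + trans(0, k);
        int arg = 0;
        for (int j = 1; j < K; ++j) {
          const double v = delta[(t - 1) * K + j] + trans(j, k);
          if (v > best) { best = v; arg = j; }
        }
        delta[t * K + k] = best + emit(off + t, k);
        psi[t * K + k] = arg;
      }
    }
    int arg = 0;
    double best = delta[(T - 1) * K];
    for (int k = 1; k < K; ++k)
      if (delta[(T - 1) * K + k] > best) { best = delta[(T - 1) * K + k]; arg = k; }
    path[off + T - 1] = arg + 1;
    for (int t = T - 1; t > 0; --t) {
      arg = psi[t * K + arg];
      path[off + t - 1] = arg + 1;
    }
  }
  return path;
}
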