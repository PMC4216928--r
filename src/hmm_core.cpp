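#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward for a single chain.
// loge: T x K log emission matrix; trans: K x K row-stochastic transition
// matrix; init: length-K initial distribution. Returns per-position
// posteriors (gamma), total log-likelihood and summed expected transition
// counts (xi).
// [[Rcpp::export(name = ".fwdback_core")]]
List fwdback_core(NumericMatrix loge, NumericMatrix trans,
                  NumericVector init) {
  const int T = loge.nrow(), K = loge.ncol();
  if (T == 0)
    return List::create(_["gamma"] = NumericMatrix(0, K),
                        _["loglik"] = 0.0,
                        _["xi"] = NumericMatrix(K, K));
  NumericMatrix e(T, K), alpha(T, K), beta(T, K), gamma(T, K), xi(K, K);
  std::vector<double> emax(T), scale(T);

  for (int t = 0; t < T; ++t) {
    double m = loge(t, 0);
    for (int k = 1; k < K; ++k) if (loge(t, k) > m) m = loge(t, k);
    emax[t] = m;
    for (int k = 0; k < K; ++k) e(t, k) = std::exp(loge(t, k) - m);
  }

  double ll = 0.0, c0 = 0.0;
  for (int k = 0; k < K; ++k) { alpha(0, k) = init[k] * e(0, k); c0 += alpha(0, k); }
  if (c0 <= 0) stop("zero forward mass at position 1");
  for (int k = 0; k < K; ++k) alpha(0, k) /= c0;
  scale[0] = c0;
  ll += std::log(c0) + emax[0];

  for (int t = 1; t < T; ++t) {
    double ct = 0.0;
    for (int j = 0; j < K; ++j) {
      double s = 0.0;
      for (int i = 0; i < K; ++i) s += alpha(t - 1, i) * trans(i, j);
      double v = s * e(t, j);
      alpha(t, j) = v;
      ct += v;
    }
    if (ct <= 0) stop("zero forward mass at position %d", t + 1);
    for (int j = 0; j < K; ++j) alpha(t, j) /= ct;
    scale[t] = ct;
    ll += std::log(ct) + emax[t];
  }

  for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int i = 0; i < K; ++i) {
      double s = 0.0;
      for (int j = 0; j < K; ++j)
        s += trans(i, j) * e(t + 1, j) * beta(t + 1, j);
      beta(t, i) = s / scale[t + 1];
    }
  }

  for (int t = 0; t < T; ++t) {
    double s = 0.0;
    for (int k = 0; k < K; ++k) { double v = alpha(t, k) * beta(t, k); gamma(t, k) = v; s += v; }
    for (int k = 0; k < K; ++k) gamma(t, k) /= s;
  }

  for (int t = 1; t < T; ++t) {
    for (int i = 0; i < K; ++i) {
      const double ai = alpha(t - 1, i);
      if (ai == 0.0) continue;
      for (int j = 0; j < K; ++j)
        xi(i, j) += ai * trans(i, j) * e(t, j) * beta(t, j) / scale[t];
    }
  }

  return List::create(_["gamma"] = gamma, _["loglik"] = ll, _["xi"] = xi);
}

// Viterbi decoding in log space. Ties are broken toward the lower state
// index (strict improvement required to replace the incumbent).
// Returns 1-based path and its joint log-probability.
// [[Rcpp::export(name = ".viterbi_core")]]
List viterbi_core(NumericMatrix loge, NumericMatrix ltrans,
                  NumericVector linit) {
  const int T = loge.nrow(), K = loge.ncol();
  if (T == 0)
    return List::create(_["path"] = IntegerVector(0), _["logprob"] = 0.0);
  NumericMatrix delta(T, K);
  IntegerMatrix psi(T, K);
  for (int k = 0; k < K; ++k) delta(0, k) = linit[k] + loge(0, k);
  for (int t = 1; t < T; ++t) {
    for (int j = 0; j < K; ++j) {
      double best = delta(t - 1, 0) + ltrans(0, j);
      int arg = 0;
      for (int i = 1; i < K; ++i) {
        const double v = delta(t - 1, i) + ltrans(i, j);
        if (v > best) { best = v; arg = i; }
      }
      delta(t, j) = best + loge(t, j);
      psi(t, j) = arg;
    }
  }
  int best = 0;
  double bv = delta(T - 1, 0);
  for (int k = 1; k < K; ++k)
    if (delta(T - 1, k) > bv) { bv = delta(T - 1, k); best = k; }
  IntegerVector path(T);
  path[T - 1] = best + 1;
  for (int t = T - 1; t > 0; --t) { best = psi(t, best); path[t - 1] = best + 1; }
  return List::create(_["path"] = path, _["logprob"] = bv);
}
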