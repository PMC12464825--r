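#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward recursions for a K-state HMM, given per-bin log
// emission densities. Rows of `logdens` that are all zero act as missing
// observations (emission likelihood 1 in every state), which keeps the
// Markov chain intact across gaps. Returns the log-likelihood, posterior
// state probabilities (gamma) and summed transition posteriors (xi).
// [[Rcpp::export]]
List hmm_forward_backward(NumericMatrix logdens, NumericMatrix trans,
                          NumericVector init) {
  const int n = logdens.nrow(), K = logdens.ncol();
  NumericMatrix e(n, K);
  NumericVector shift(n);
  for (int t = 0; t < n; ++t) {
    double m = logdens(t, 0);
    for (int s = 1; s < K; ++s) m = std::max(m, logdens(t, s));
    shift[t] = m;
    for (int s = 0; s < K; ++s) e(t, s) = std::exp(logdens(t, s) - m);
  }

  NumericMatrix alpha(n, K), beta(n, K);
  NumericVector c(n);
  for (int s = 0; s < K; ++s) alpha(0, s) = init[s] * e(0, s);
  double c0 = 0;
  for (int s = 0; s < K; ++s) c0 += alpha(0, s);
  c[0] = c0;
  for (int s = 0; s < K; ++s) alpha(0, s) /= c0;
  for (int t = 1; t < n; ++t) {
    double ct = 0;
    for (int s = 0; s < K; ++s) {
      double a = 0;
      for (int i = 0; i < K; ++i) a += alpha(t - 1, i) * trans(i, s);
      a *= e(t, s);
      alpha(t, s) = a;
      ct += a;
    }
    c[t] = ct;
    for (int s = 0; s < K; ++s) alpha(t, s) /= ct;
  }

  for (int s = 0; s < K; ++s) beta(n - 1, s) = 1.0;
  for (int t = n - 2; t >= 0; --t) {
    for (int s = 0; s < K; ++s) {
      double b = 0;
      for (int j = 0; j < K; ++j)
        b += trans(s, j) * e(t + 1, j) * beta(t + 1, j);
      beta(t, s) = b / c[t + 1];
    }
  }

  NumericMatrix gamma(n, K), xi(K, K);
  for (int t = 0; t < n; ++t)
    for (int s = 0; s < K; ++s) gamma(t, s) = alpha(t, s) * beta(t, s);
  for (int t = 0; t < n - 1; ++t)
    for (int i = 0; i < K; ++i)
      for (int j = 0; j < K; ++j)
        xi(i, j) += alpha(t, i) * trans(i, j) * e(t + 1, j) *
                    beta(t + 1, j) / c[t + 1];

  double ll = 0;
  for (int t = 0; t < n; ++t) ll += std::log(c[t]) + shift[t];
  return List::create(_["loglik"] = ll, _["gamma"] = gamma, _["xi"] = xi,
                      _["gamma1"] = gamma(0, _));
}

// Most probable state path (Viterbi), 1-based state indices.
// [[Rcpp::export]]
IntegerVector hmm_viterbi(NumericMatrix logdens, NumericMatrix trans,
                          NumericVector init) {
  const int n = logdens.nrow(), K = logdens.ncol();
  NumericMatrix delta(n, K);
  IntegerMatrix psi(n, K);
  for (int s = 0; s < K; ++s)
    delta(0, s) = std::log(init[s]) + logdens(0, s);
  for (int t = 1; t < n; ++t) {
    for (int s = 0; s < K; ++s) {
      double best = R_NegInf;
      int arg = 0;
      for (int i = 0; i < K; ++i) {
        double v = delta(t - 1, i) + std::log(trans(i, s));
        if (v > best) { best = v; arg = i; }
      }
      delta(t, s) = best + logdens(t, s);
      psi(t, s) = arg;
    }
  }
  IntegerVector path(n);
  int last = 0;
  double best = delta(n - 1, 0);
  for (int s = 1; s < K; ++s)
    if (delta(n - 1, s) > best) { best = delta(n - 1, s); last = s; }
  path[n - 1] = last + 1;
  for (int t = n - 2; t >= 0; --t) {
    last = psi(t + 1, last);
    path[t] = last + 1;
  }
  return path;
}
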