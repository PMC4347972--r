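#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward recursions for one observation sequence with a
// fixed log-emission matrix. Per-position scaling keeps all quantities in
// the linear domain without underflow; the per-position log-emission row
// maximum is factored out first so exp() never underflows for the state
// that carries the mass.
//
// logE: T x K log emission densities, A: K x K row-stochastic transition
// matrix, pi: length-K initial distribution.
//
// Returns gamma (T x K posteriors, rows sum to 1), xi (K x K expected
// transition counts summed over t), and the sequence log-likelihood.
// [[Rcpp::export(name = ".fbScaled")]]
List fbScaled(const NumericMatrix& logE, const NumericMatrix& A,
              const NumericVector& pi) {
  const int T = logE.nrow(), K = logE.ncol();
  if (A.nrow() != K || A.ncol() != K || pi.size() != K)
    stop("dimension mismatch between emissions, transition and initial");

  NumericVector m(T);
  NumericMatrix e(T, K);
  for (int t = 0; t < T; ++t) {
    double mx = R_NegInf;
    for (int k = 0; k < K; ++k) mx = std::max(mx, logE(t, k));
    if (!R_FINITE(mx))
      stop("observation at position %d has zero density in every state",
           t + 1);
    m[t] = mx;
    for (int k = 0; k < K; ++k) e(t, k) = std::exp(logE(t, k) - mx);
  }

  NumericMatrix alpha(T, K);
  NumericVector c(T);
  for (int k = 0; k < K; ++k) alpha(0, k) = pi[k] * e(0, k);
  double c0 = 0.0;
  for (int k = 0; k < K; ++k) c0 += alpha(0, k);
  if (c0 <= 0.0) stop("zero forward mass at position 1");
  c[0] = c0;
  for (int k = 0; k < K; ++k) alpha(0, k) /= c0;

  for (int t = 1; t < T; ++t) {
    double ct = 0.0;
    for (int k = 0; k < K; ++k) {
      double s = 0.0;
      for (int i = 0; i < K; ++i) s += alpha(t - 1, i) * A(i, k);
      s *= e(t, k);
      alpha(t, k) = s;
      ct += s;
    }
    if (ct <= 0.0) stop("zero forward mass at position %d", t + 1);
    c[t] = ct;
    for (int k = 0; k < K; ++k) alpha(t, k) /= ct;
  }

  NumericMatrix beta(T, K);
  for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int i = 0; i < K; ++i) {
      double s = 0.0;
      for (int k = 0; k < K; ++k)
        s += A(i, k) * e(t + 1, k) * beta(t + 1, k);
      beta(t, i) = s / c[t + 1];
    }
  }

  NumericMatrix gamma(T, K);
  for (int t = 0; t < T; ++t) {
    double s = 0.0;
    for (int k = 0; k < K; ++k) {
      gamma(t, k) = alpha(t, k) * beta(t, k);
      s += gamma(t, k);
    }
    for (int k = 0; k < K; ++k) gamma(t, k) /= s;
  }

  NumericMatrix xi(K, K);
  for (int t = 0; t + 1 < T; ++t)
    for (int i = 0; i < K; ++i) {
      const double ai = alpha(t, i);
      for (int j = 0; j < K; ++j)
        xi(i, j) += ai * A(i, j) * e(t + 1, j) * beta(t + 1, j) / c[t + 1];
    }

  double loglik = 0.0;
  for (int t = 0; t < T; ++t) loglik += std::log(c[t]) + m[t];

  return List::create(_["gamma"] = gamma, _["xi"] = xi,
                      _["loglik"] = loglik);
}
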