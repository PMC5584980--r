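#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// EM for a mixture of position-independent PWMs over the 20-letter
// amino-acid alphabet.
//
// idx    : n x L integer matrix of 1-based residue indices
// r_init : n x C initial responsibilities (rows sum to 1), where C = K
//          motif components plus, if trash is true, one final flat
//          background component with fixed uniform emissions (only its
//          mixing weight is free)
// gamma  : Dirichlet smoothing count added per residue per position in the
//          M-step (keeps emission probabilities strictly positive)
// Iterates M-step (from current responsibilities) then E-step, tracking the
// observed-data log-likelihood; stops when the relative change drops below
// rel_tol or after max_iter iterations.
//
// Internally both the count and log-PWM tables use a [position][residue]
// [component] layout so the per-peptide inner loops run contiguously over
// components.
// [[Rcpp::export(name = ".em_fit_cpp")]]
List em_fit_cpp(IntegerMatrix idx, NumericMatrix r_init, double gamma,
                int max_iter, double rel_tol, bool trash = false) {
  const int n = idx.nrow(), L = idx.ncol();
  const int C = r_init.ncol();           // total components
  const int K = trash ? C - 1 : C;       // motif components
  if (K < 1) stop("need at least one motif component");
  if (r_init.nrow() != n) stop("r_init must have one row per peptide");

  // peptide-major copy of the residue indices (0-based)
  std::vector<int> x((size_t)n * L);
  for (int i = 0; i < L; ++i)
    for (int p = 0; p < n; ++p)
      x[(size_t)p * L + i] = idx(p, i) - 1;

  // peptide-major responsibilities (all C components)
  std::vector<double> r((size_t)n * C);
  for (int k = 0; k < C; ++k)
    for (int p = 0; p < n; ++p)
      r[(size_t)p * C + k] = r_init(p, k);

  const double log_flat = -(double)L * std::log(20.0);
  // tables in [i][a][k] layout, K motif components
  std::vector<double> cnt((size_t)L * 20 * K);
  std::vector<double> logpwm((size_t)L * 20 * K);
  std::vector<double> w(C, 1.0 / C), logw(C), rsum(C), logp(C);
  std::vector<double> ll_trace;
  double ll = R_NegInf;
  int iter = 0;

  for (iter = 1; iter <= max_iter; ++iter) {
    // ---- M-step ----
    std::fill(cnt.begin(), cnt.end(), 0.0);
    std::fill(rsum.begin(), rsum.end(), 0.0);
    for (int p = 0; p < n; ++p) {
      const double *rp = &r[(size_t)p * C];
      const int *xp = &x[(size_t)p * L];
      for (int i = 0; i < L; ++i) {
        double *col = &cnt[((size_t)i * 20 + xp[i]) * K];
        for (int k = 0; k < K; ++k) col[k] += rp[k];
      }
      for (int k = 0; k < C; ++k) rsum[k] += rp[k];
    }
    for (int k = 0; k < C; ++k) w[k] = rsum[k] / n;
    const double denom_add = 20.0 * gamma;
    for (int k = 0; k < K; ++k) {
      const double denom = rsum[k] + denom_add;
      for (int i = 0; i < L; ++i)
        for (int a = 0; a < 20; ++a) {
          double &v = cnt[((size_t)i * 20 + a) * K + k];
          v = denom > 0 ? (v + gamma) / denom : 1.0 / 20.0;
        }
    }

    // ---- E-step (+ log-likelihood) ----
    for (size_t t = 0; t < cnt.size(); ++t)
      logpwm[t] = cnt[t] > 0 ? std::log(cnt[t]) : R_NegInf;
    for (int k = 0; k < C; ++k)
      logw[k] = w[k] > 0 ? std::log(w[k]) : R_NegInf;

    double ll_new = 0.0;
    for (int p = 0; p < n; ++p) {
      const int *xp = &x[(size_t)p * L];
      for (int k = 0; k < K; ++k) logp[k] = logw[k];
      for (int i = 0; i < L; ++i) {
        const double *row = &logpwm[((size_t)i * 20 + xp[i]) * K];
        for (int k = 0; k < K; ++k) logp[k] += row[k];
      }
      if (trash) logp[K] = logw[K] + log_flat;
      double mx = R_NegInf;
      for (int k = 0; k < C; ++k) if (logp[k] > mx) mx = logp[k];
      if (!R_FINITE(mx)) stop("all mixture components have zero likelihood");
      double z = 0.0;
      for (int k = 0; k < C; ++k) {
        logp[k] = R_FINITE(logp[k]) ? std::exp(logp[k] - mx) : 0.0;
        z += logp[k];
      }
      double *rp = &r[(size_t)p * C];
      for (int k = 0; k < C; ++k) rp[k] = logp[k] / z;
      ll_new += mx + std::log(z);
    }
    ll_trace.push_back(ll_new);
    if (R_FINITE(ll) &&
        std::fabs(ll_new - ll) < rel_tol * std::fabs(ll)) {
      ll = ll_new;
      break;
    }
    ll = ll_new;
  }

  NumericMatrix r_out(n, C);
  for (int k = 0; k < C; ++k)
    for (int p = 0; p < n; ++p)
      r_out(p, k) = r[(size_t)p * C + k];
  List pwm_list(K);
  for (int k = 0; k < K; ++k) {
    NumericMatrix m(L, 20);
    for (int i = 0; i < L; ++i)
      for (int a = 0; a < 20; ++a)
        m(i, a) = cnt[((size_t)i * 20 + a) * K + k];
    pwm_list[k] = m;
  }
  return List::create(_["pwms"] = pwm_list,
                      _["weights"] = NumericVector(w.begin(), w.end()),
                      _["responsibilities"] = r_out,
                      _["log_likelihood"] = ll,
                      _["ll_trace"] = NumericVector(ll_trace.begin(), ll_trace.end()),
                      _["n_iter"] = std::min(iter, max_iter));
}
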