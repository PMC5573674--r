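#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Lea-Coulson (MSS) probability mass function of mutant counts per culture.
// p0 = exp(-m); p_n = (m/n) * sum_{k=0}^{n-1} p_k / (n - k + 1).
// O(n_max^2); kept in C++ because the MLE evaluates it repeatedly with
// n_max up to the truncation cap (default 1e4).
// [[Rcpp::export(name = ".ld_pmf_c")]]
NumericVector ld_pmf_c(double m, int n_max) {
  if (m < 0) stop("m must be non-negative");
  if (n_max < 0) stop("n_max must be non-negative");
  NumericVector p(n_max + 1);
  p[0] = std::exp(-m);
  for (int n = 1; n <= n_max; ++n) {
    double s = 0.0;
    for (int k = 0; k < n; ++k) s += p[k] / (double)(n - k + 1);
    p[n] = m / (double)n * s;
  }
  return p;
}

// Log-likelihood of observed mutant counts under the Lea-Coulson pmf.
// `counts` must already be capped at `cap`; counts equal to cap are treated
// as the ">= cap" tail cell with probability 1 - sum_{n<cap} p_n.
// [[Rcpp::export(name = ".ld_loglik_c")]]
double ld_loglik_c(double m, IntegerVector counts, int cap) {
  int mx = 0;
  bool any_tail = false;
  for (int i = 0; i < counts.size(); ++i) {
    if (counts[i] >= cap) any_tail = true;
    else if (counts[i] > mx) mx = counts[i];
  }
  int need = any_tail ? (cap - 1) : mx;
  NumericVector p = ld_pmf_c(m, need);
  double tail = 0.0;
  if (any_tail) {
    double s = 0.0;
    for (int n = 0; n < cap; ++n) s += p[n];
    tail = 1.0 - s;
    if (tail < 1e-300) tail = 1e-300;
  }
  double ll = 0.0;
  for (int i = 0; i < counts.size(); ++i) {
    double pi = (counts[i] >= cap) ? tail : p[counts[i]];
    if (pi < 1e-300) pi = 1e-300;
    ll += std::log(pi);
  }
  return ll;
}
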