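// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

// qGGMRF neighborhood penalty over the 26-neighbor (1-hop) 3-D neighborhood:
//   rho(d) = |d/sigma|^2 / (c + |d/sigma|^(2-p))
// summed over ordered voxel pairs with partition-of-unity weights
// proportional to 1 / ||offset||. Out-of-range neighbors are skipped and the
// remaining weights are not renormalized at boundaries. Each unordered pair
// is visited once (13 half-space offsets, contiguous first-dimension inner
// loops over raw pointers) and counted twice, matching the ordered-pair
// energy; the gradient accumulates both endpoints.
// [[Rcpp::export]]
Rcpp::List cpp_qggmrf_eval(const arma::cube& f, double sigma, double p,
                           double cpar, bool want_grad) {
  const int d1 = f.n_rows, d2 = f.n_cols, d3 = f.n_slices;
  const double zsum = 6.0 + 12.0 / std::sqrt(2.0) + 8.0 / std::sqrt(3.0);
  const double inv_s2 = 1.0 / (sigma * sigma);
  const double hep = 0.5 * (2.0 - p);      // exponent of (d/sigma)^2

  double value = 0.0;
  arma::cube grad;
  if (want_grad) grad.zeros(d1, d2, d3);
  const double* fp = f.memptr();
  double* gp = want_grad ? grad.memptr() : nullptr;

  for (int oc = 0; oc <= 1; ++oc) {
    for (int ob = (oc == 0) ? 0 : -1; ob <= 1; ++ob) {
      for (int oa = (oc == 0 && ob == 0) ? 1 : -1; oa <= 1; ++oa) {
        const double dist = std::sqrt((double)(oa * oa + ob * ob + oc * oc));
        const double wgt = 2.0 * (1.0 / dist) / zsum;  // ordered-pair count
        const long long shift = (long long)oa + (long long)d1 *
          ((long long)ob + (long long)d2 * (long long)oc);
        const int a0 = std::max(0, -oa), a1 = d1 - 1 - std::max(0, oa);
        const int b0 = std::max(0, -ob), b1 = d2 - 1 - std::max(0, ob);
        const int c0 = std::max(0, -oc), c1 = d3 - 1 - std::max(0, oc);
        for (int c = c0; c <= c1; ++c) {
          for (int b = b0; b <= b1; ++b) {
            const long long base = (long long)d1 * (b + (long long)d2 * c);
            const double* row = fp + base;
            const double* nbr = fp + base + shift;
            double* grow = want_grad ? gp + base : nullptr;
            for (int a = a0; a <= a1; ++a) {
              const double delta = row[a] - nbr[a];
              const double as2 = delta * delta * inv_s2;
              const double t = (as2 > 0.0) ? std::pow(as2, hep) : 0.0;
              const double den = cpar + t;
              value += wgt * as2 / den;
              if (want_grad) {
                const double rd =
                    delta * inv_s2 * (2.0 * cpar + p * t) / (den * den);
                grow[a] += wgt * rd;
                grow[a + shift] -= wgt * rd;
              }
            }
          }
        }
      }
    }
  }
  if (want_grad)
    return Rcpp::List::create(Rcpp::Named("value") = value,
                              Rcpp::Named("gradient") = grad);
  return Rcpp::List::create(Rcpp::Named("value") = value);
}
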