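// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

// Exponential-of-semicircle spreading kernel on support |d| <= w/2.
static inline double es_kernel(double d, double halfw, double beta) {
  double t = d / halfw;
  double s = 1.0 - t * t;
  if (s <= 0.0) return 0.0;
  return std::exp(beta * (std::sqrt(s) - 1.0));
}

static inline int wrap_index(int j, int nf) {
  int r = j % nf;
  return (r < 0) ? r + nf : r;
}

// Type-2 step: deapodize a real n x n image, embed into the nf x nf fine grid,
// 2-D FFT, then kernel-weighted interpolation at the non-uniform frequency
// points (xi in fine-grid frequency units, periodic in nf). Pixel index s0
// is embedded at fine index 0 so image coordinates stay within [-n/2, n/2)
// where the deapodization profile is well conditioned; the residual
// half-pixel center phase is applied by the caller.
// [[Rcpp::export]]
arma::cx_vec cpp_nufft_type2(const arma::mat& img, const arma::vec& deapod,
                             const arma::vec& xix, const arma::vec& xiy,
                             int nf, int w, double beta, int s0) {
  const int n = img.n_rows;
  arma::cx_mat fine(nf, nf, arma::fill::zeros);
  for (int x = 0; x < n; ++x) {
    const int ix = wrap_index(x - s0, nf);
    for (int y = 0; y < n; ++y)
      fine(wrap_index(y - s0, nf), ix) = img(y, x) / (deapod[y] * deapod[x]);
  }
  fine = arma::fft2(fine);

  const int m = xix.n_elem;
  const double halfw = 0.5 * w;
  arma::cx_vec out(m);
  std::vector<double> wx(w + 2), wy(w + 2);
  for (int j = 0; j < m; ++j) {
    const double cx = xix[j], cy = xiy[j];
    const int jx0 = (int)std::ceil(cx - halfw), jx1 = (int)std::floor(cx + halfw);
    const int jy0 = (int)std::ceil(cy - halfw), jy1 = (int)std::floor(cy + halfw);
    for (int a = jx0; a <= jx1; ++a) wx[a - jx0] = es_kernel(cx - a, halfw, beta);
    for (int b = jy0; b <= jy1; ++b) wy[b - jy0] = es_kernel(cy - b, halfw, beta);
    std::complex<double> acc(0.0, 0.0);
    for (int a = jx0; a <= jx1; ++a) {
      const int ia = wrap_index(a, nf);
      std::complex<double> col(0.0, 0.0);
      for (int b = jy0; b <= jy1; ++b)
        col += wy[b - jy0] * fine(wrap_index(b, nf), ia);
      acc += wx[a - jx0] * col;
    }
    out[j] = acc;
  }
  return out;
}

// Type-1 step: exact adjoint of cpp_nufft_type2. Spread coefficients onto the
// fine frequency grid with the same kernel, unnormalized inverse 2-D FFT,
// crop to n x n, deapodize, real part.
// [[Rcpp::export]]
arma::mat cpp_nufft_type1(const arma::cx_vec& coef, const arma::vec& deapod,
                          const arma::vec& xix, const arma::vec& xiy,
                          int n, int nf, int w, double beta, int s0) {
  arma::cx_mat fine(nf, nf, arma::fill::zeros);
  const int m = coef.n_elem;
  const double halfw = 0.5 * w;
  std::vector<double> wx(w + 2), wy(w + 2);
  for (int j = 0; j < m; ++j) {
    const double cx = xix[j], cy = xiy[j];
    const int jx0 = (int)std::ceil(cx - halfw), jx1 = (int)std::floor(cx + halfw);
    const int jy0 = (int)std::ceil(cy - halfw), jy1 = (int)std::floor(cy + halfw);
    for (int a = jx0; a <= jx1; ++a) wx[a - jx0] = es_kernel(cx - a, halfw, beta);
    for (int b = jy0; b <= jy1; ++b) wy[b - jy0] = es_kernel(cy - b, halfw, beta);
    const std::complex<double> cj = coef[j];
    for (int a = jx0; a <= jx1; ++a) {
      const int ia = wrap_index(a, nf);
      const std::complex<double> ca = cj * wx[a - jx0];
      for (int b = jy0; b <= jy1; ++b)
        fine(wrap_index(b, nf), ia) += wy[b - jy0] * ca;
    }
  }
  fine = arma::ifft2(fine) * ((double)nf * (double)nf);
  arma::mat out(n, n);
  for (int x = 0; x < n; ++x) {
    const int ix = wrap_index(x - s0, nf);
    for (int y = 0; y < n; ++y)
      out(y, x) = std::real(fine(wrap_index(y - s0, nf), ix)) / (deapod[y] * deapod[x]);
  }
  return out;
}

// Kernel profile, exposed for the deapodization quadrature and tests.
// [[Rcpp::export]]
arma::vec cpp_es_kernel(const arma::vec& d, int w, double beta) {
  arma::vec out(d.n_elem);
  const double halfw = 0.5 * w;
  for (arma::uword i = 0; i < d.n_elem; ++i) out[i] = es_kernel(d[i], halfw, beta);
  return out;
}
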