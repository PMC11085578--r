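// Non-uniform DFT kernels for the radial k-space simulator and the gridding
// reconstruction. The forward/adjoint transforms are exact sums (no kernel
// approximation); the spreading routine implements the Kaiser-Bessel
// convolution step of the gridding (adjoint NUFFT) reconstruction.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double TWO_PI = 6.283185307179586476925286766559;

// S_j = sum_v a_v * exp(-2*pi*i * k_j . x_v)
// coords: Nv x 3 (metres), k: Ns x 3 (cycles/m), amp: complex Nv
// [[Rcpp::export]]
arma::cx_vec cppNudftForward(const arma::mat& coords,
                             const arma::cx_vec& amp,
                             const arma::mat& k) {
  const arma::uword nv = coords.n_rows, ns = k.n_rows;
  if (amp.n_elem != nv) stop("amplitude length does not match coordinate count");
  arma::cx_vec out(ns, arma::fill::zeros);
  for (arma::uword j = 0; j < ns; ++j) {
    const double kx = k(j, 0), ky = k(j, 1), kz = k(j, 2);
    std::complex<double> acc(0.0, 0.0);
    for (arma::uword v = 0; v < nv; ++v) {
      const double ph = -TWO_PI * (kx * coords(v, 0) + ky * coords(v, 1) + kz * coords(v, 2));
      acc += amp(v) * std::complex<double>(std::cos(ph), std::sin(ph));
    }
    out(j) = acc;
  }
  return out;
}

// I_v = sum_j y_j * exp(+2*pi*i * k_j . x_v)   (true adjoint of the forward)
// [[Rcpp::export]]
arma::cx_vec cppNudftAdjoint(const arma::mat& k,
                             const arma::cx_vec& y,
                             const arma::mat& coords) {
  const arma::uword nv = coords.n_rows, ns = k.n_rows;
  if (y.n_elem != ns) stop("sample length does not match k-space coordinate count");
  arma::cx_vec out(nv, arma::fill::zeros);
  for (arma::uword v = 0; v < nv; ++v) {
    const double x = coords(v, 0), yy = coords(v, 1), z = coords(v, 2);
    std::complex<double> acc(0.0, 0.0);
    for (arma::uword j = 0; j < ns; ++j) {
      const double ph = TWO_PI * (k(j, 0) * x + k(j, 1) * yy + k(j, 2) * z);
      acc += y(j) * std::complex<double>(std::cos(ph), std::sin(ph));
    }
    out(v) = acc;
  }
  return out;
}

static inline double kbKernel(double kappa, double halfWidth, double beta) {
  const double r = kappa / halfWidth;
  const double t = 1.0 - r * r;
  if (t <= 0.0) return 0.0;
  return R::bessel_i(beta * std::sqrt(t), 0.0, 1.0);
}

// Spread weighted complex samples onto an oversampled Cartesian grid with a
// finite-support Kaiser-Bessel kernel. u: Ns x 3 sample positions in grid
// units (origin at grid index 0, wrap-around/periodic); g: grid size per axis.
// Returns a complex vector of length g^3 in column-major (x fastest) order.
// [[Rcpp::export]]
arma::cx_vec cppKbSpread(const arma::mat& u,
                         const arma::cx_vec& y,
                         const int g,
                         const double width,
                         const double beta) {
  const arma::uword ns = u.n_rows;
  if (y.n_elem != ns) stop("sample length does not match sample position count");
  const double hw = width / 2.0;
  const int lo = (int)std::ceil(-hw), hi = (int)std::floor(hw);
  const int nk = hi - lo + 1;
  arma::cx_vec grid((arma::uword)g * g * g, arma::fill::zeros);
  std::vector<double> wx(nk), wy(nk), wz(nk);
  std::vector<int> ix(nk), iy(nk), iz(nk);
  for (arma::uword j = 0; j < ns; ++j) {
    for (int ax = 0; ax < 3; ++ax) {
      const double uu = u(j, ax);
      const int base = (int)std::floor(uu);
      std::vector<double>& w = (ax == 0) ? wx : (ax == 1) ? wy : wz;
      std::vector<int>& idx = (ax == 0) ? ix : (ax == 1) ? iy : iz;
      for (int o = 0; o < nk; ++o) {
        const int p = base + lo + o;
        const double kap = uu - p;
        w[o] = (std::fabs(kap) <= hw) ? kbKernel(kap, hw, beta) : 0.0;
        int pm = p % g;
        if (pm < 0) pm += g;
        idx[o] = pm;
      }
    }
    const std::complex<double> yj = y(j);
    for (int oz = 0; oz < nk; ++oz) {
      if (wz[oz] == 0.0) continue;
      const arma::uword zoff = (arma::uword)iz[oz] * g * g;
      for (int oy = 0; oy < nk; ++oy) {
        const double wyz = wy[oy] * wz[oz];
        if (wyz == 0.0) continue;
        const arma::uword yoff = zoff + (arma::uword)iy[oy] * g;
        for (int ox = 0; ox < nk; ++ox) {
          if (wx[ox] == 0.0) continue;
          grid(yoff + ix[ox]) += yj * (wx[ox] * wyz);
        }
      }
    }
  }
  return grid;
}
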