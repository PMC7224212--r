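#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Robust locally weighted linear regression (LOWESS) of a scalar field
// sampled on a regular 2D/3D grid, restricted to a pixel mask.
//
// For every masked pixel the k nearest masked pixels (physical distance,
// anisotropic spacing respected) form the local window; a tricube-weighted
// linear fit evaluated at the pixel gives the smoothed value.  With
// robust_iters > 0 the fit is repeated with bisquare robustness weights
// computed from the previous pass's residuals, which approximates a
// least-absolute-residual local fit and makes the smoother resistant to
// displacement outliers.  Pixels outside the mask never enter any window.
//
// values/mask are in R's column-major layout; dims has length 2 or 3.
// [[Rcpp::export(name = ".lowess_grid_cpp")]]
NumericVector lowess_grid_cpp(NumericVector values, LogicalVector mask,
                              IntegerVector dims, NumericVector spacing,
                              int k, int robust_iters) {
  const int nd = dims.size();
  if (nd < 1 || nd > 3) stop("grid must be 1D, 2D or 3D");
  int d0 = dims[0], d1 = (nd > 1 ? dims[1] : 1), d2 = (nd > 2 ? dims[2] : 1);
  const R_xlen_t n = values.size();
  double s0 = spacing[0], s1 = (nd > 1 ? spacing[1] : 1.0),
         s2 = (nd > 2 ? spacing[2] : 1.0);

  std::vector<R_xlen_t> masked;
  masked.reserve(n);
  for (R_xlen_t i = 0; i < n; ++i) if (mask[i]) masked.push_back(i);
  const R_xlen_t nm = (R_xlen_t)masked.size();
  if (nm == 0) stop("empty mask");
  if (k > (int)nm) k = (int)nm;
  if (k < nd + 2) k = std::min<int>((int)nm, nd + 2);

  // robustness weights, indexed per masked pixel
  std::vector<double> rw(nm, 1.0), fitted(nm, 0.0), resid(nm, 0.0);
  std::vector<R_xlen_t> idx_of(n, -1);
  for (R_xlen_t m = 0; m < nm; ++m) idx_of[masked[m]] = m;

  const int np = nd + 1;  // intercept + slopes
  std::vector<double> A(np * np), b(np);

  for (int pass = 0; pass <= robust_iters; ++pass) {
    for (R_xlen_t m = 0; m < nm; ++m) {
      R_xlen_t lin = masked[m];
      int i0 = (int)(lin % d0);
      int i1 = (int)((lin / d0) % d1);
      int i2 = (int)(lin / ((R_xlen_t)d0 * d1));

      // expand a Chebyshev box until it holds >= k masked pixels
      std::vector<std::pair<double, R_xlen_t>> cand;  // (dist^2, masked-index)
      int r = 1;
      int rmax = std::max(std::max(d0, d1), d2);
      while (true) {
        cand.clear();
        int a0 = std::max(0, i0 - r), b0 = std::min(d0 - 1, i0 + r);
        int a1 = std::max(0, i1 - r), b1 = std::min(d1 - 1, i1 + r);
        int a2 = std::max(0, i2 - r), b2 = std::min(d2 - 1, i2 + r);
        for (int z = a2; z <= b2; ++z)
          for (int y = a1; y <= b1; ++y) {
            R_xlen_t base = (R_xlen_t)z * d0 * d1 + (R_xlen_t)y * d0;
            for (int x = a0; x <= b0; ++x) {
              R_xlen_t j = base + x;
              if (!mask[j]) continue;
              double dx = (x - i0) * s0, dy = (y - i1) * s1, dz = (z - i2) * s2;
              cand.push_back({dx * dx + dy * dy + dz * dz, idx_of[j]});
            }
          }
        if ((int)cand.size() >= k || r >= rmax) break;
        ++r;
      }
      int kk = std::min<int>(k, (int)cand.size());
      std::partial_sort(cand.begin(), cand.begin() + kk, cand.end());
      double dmax = std::sqrt(cand[kk - 1].first);
      if (dmax <= 0) dmax = 1.0;

      // weighted least squares: value ~ 1 + dx + dy (+ dz)
      std::fill(A.begin(), A.end(), 0.0);
      std::fill(b.begin(), b.end(), 0.0);
      for (int c = 0; c < kk; ++c) {
        R_xlen_t mj = cand[c].second;
        R_xlen_t j = masked[mj];
        int j0 = (int)(j % d0);
        int j1 = (int)((j / d0) % d1);
        int j2 = (int)(j / ((R_xlen_t)d0 * d1));
        double x[4] = {1.0, (j0 - i0) * s0, (j1 - i1) * s1, (j2 - i2) * s2};
        double u = std::sqrt(cand[c].first) / dmax;
        double t = 1.0 - u * u * u;
        double w = t * t * t;                       // tricube
        if (pass > 0) w *= rw[mj];                  // bisquare robustness
        if (w <= 0) continue;
        double v = values[j];
        for (int p = 0; p < np; ++p) {
          b[p] += w * x[p] * v;
          for (int q = 0; q <= p; ++q) A[p * np + q] += w * x[p] * x[q];
        }
      }
      for (int p = 0; p < np; ++p)
        for (int q = p + 1; q < np; ++q) A[p * np + q] = A[q * np + p];
      // ridge-free Cholesky solve of the tiny normal system, with a fallback
      // to the weighted mean when the window is degenerate
      double L[16];
      bool ok = true;
      for (int p = 0; p < np && ok; ++p) {
        for (int q = 0; q <= p; ++q) {
          double s = A[p * np + q];
          for (int t2 = 0; t2 < q; ++t2) s -= L[p * 4 + t2] * L[q * 4 + t2];
          if (p == q) {
            if (s <= 1e-12 * (std::abs(A[p * np + p]) + 1e-300)) { ok = false; break; }
            L[p * 4 + p] = std::sqrt(s);
          } else L[p * 4 + q] = s / L[q * 4 + q];
        }
      }
      double fit;
      if (ok) {
        double y1[4], beta[4];
        for (int p = 0; p < np; ++p) {
          double s = b[p];
          for (int q = 0; q < p; ++q) s -= L[p * 4 + q] * y1[q];
          y1[p] = s / L[p * 4 + p];
        }
        for (int p = np - 1; p >= 0; --p) {
          double s = y1[p];
          for (int q = p + 1; q < np; ++q) s -= L[q * 4 + p] * beta[q];
          beta[p] = s / L[p * 4 + p];
        }
        fit = beta[0];  // evaluated at the centre pixel (all regressors 0)
      } else {
        fit = (A[0] > 0) ? b[0] / A[0] : values[lin];
      }
      fitted[m] = fit;
      resid[m] = values[lin] - fit;
    }
    if (pass < robust_iters) {
      // bisquare weights scaled by 6 * median absolute residual
      std::vector<double> ar(nm);
      for (R_xlen_t m = 0; m < nm; ++m) ar[m] = std::abs(resid[m]);
      std::vector<double> tmp(ar);
      std::nth_element(tmp.begin(), tmp.begin() + nm / 2, tmp.end());
      double mad6 = 6.0 * tmp[nm / 2];
      // floor the scale at a tenth of the worst residual: when most
      // residuals are (numerically) zero the plain MAD rule oscillates
      // between excluding an isolated spike and readmitting it; the floor
      // keeps spikes excluded while leaving noisy data (MAD >> max/60)
      // untouched
      double mx = 0.0;
      for (R_xlen_t m = 0; m < nm; ++m) if (ar[m] > mx) mx = ar[m];
      if (mad6 < 0.1 * mx) mad6 = 0.1 * mx;
      if (mad6 <= 0) break;  // perfect fit everywhere
      for (R_xlen_t m = 0; m < nm; ++m) {
        double u = ar[m] / mad6;
        rw[m] = (u < 1.0) ? (1 - u * u) * (1 - u * u) : 0.0;
      }
    }
  }

  NumericVector out(n, NA_REAL);
  for (R_xlen_t m = 0; m < nm; ++m) out[masked[m]] = fitted[m];
  out.attr("dim") = dims;
  return out;
}
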