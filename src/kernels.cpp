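#include <RcppArmadillo.h>
#include <cfloat>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Feature-map layout throughout: column-major array of dim (H, W, C, N).
// Kernels: (kh, kw, Cin, Cout). Convolution is im2col + GEMM: patch matrix
// P is (Ho*Wo) x (kh*kw*Cin) with column order matching the column-major
// flattening of the kernel.

static inline int out_extent(int n, int k, int pad, int stride) {
  return (n + 2 * pad - k) / stride + 1;
}

static void im2col(const double *x, int H, int W, int C,
                   int kh, int kw, int stride, int pad,
                   int Ho, int Wo, arma::mat &P) {
  int col = 0;
  for (int ci = 0; ci < C; ++ci) {
    const double *xc = x + static_cast<R_xlen_t>(ci) * W * H;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i, ++col) {
        double *pc = P.colptr(col);
        for (int wo = 0; wo < Wo; ++wo) {
          const int wx = wo * stride - pad + j;
          double *pcw = pc + static_cast<R_xlen_t>(wo) * Ho;
          if (wx < 0 || wx >= W) {
            std::fill(pcw, pcw + Ho, 0.0);
            continue;
          }
          const double *xcw = xc + static_cast<R_xlen_t>(wx) * H;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hx = ho * stride - pad + i;
            pcw[ho] = (hx < 0 || hx >= H) ? 0.0 : xcw[hx];
          }
        }
      }
    }
  }
}

static void col2im_add(const arma::mat &P, int H, int W, int C,
                       int kh, int kw, int stride, int pad,
                       int Ho, int Wo, double *gx) {
  int col = 0;
  for (int ci = 0; ci < C; ++ci) {
    double *xc = gx + static_cast<R_xlen_t>(ci) * W * H;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i, ++col) {
        const double *pc = P.colptr(col);
        for (int wo = 0; wo < Wo; ++wo) {
          const int wx = wo * stride - pad + j;
          if (wx < 0 || wx >= W) continue;
          const double *pcw = pc + static_cast<R_xlen_t>(wo) * Ho;
          double *xcw = xc + static_cast<R_xlen_t>(wx) * H;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hx = ho * stride - pad + i;
            if (hx >= 0 && hx < H) xcw[hx] += pcw[ho];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
List conv2d_fwd(NumericVector x, IntegerVector xdim,
                NumericVector w, IntegerVector wdim,
                NumericVector bias, int stride, int pad, bool keep_patches) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int kh = wdim[0], kw = wdim[1], Ci = wdim[2], Co = wdim[3];
  if (Ci != C) stop("channel mismatch in conv2d");
  const int Ho = out_extent(H, kh, pad, stride);
  const int Wo = out_extent(W, kw, pad, stride);
  const arma::uword prows = static_cast<arma::uword>(Ho) * Wo;
  const arma::uword pcols = static_cast<arma::uword>(kh) * kw * Ci;
  NumericVector y(static_cast<R_xlen_t>(Ho) * Wo * Co * N);
  // the patch matrices are reused by the backward pass when requested
  NumericVector pm(keep_patches ? static_cast<R_xlen_t>(prows) * pcols * N
                                : static_cast<R_xlen_t>(prows) * pcols);
  const arma::mat Wm(const_cast<double *>(w.begin()), pcols, Co, false, true);
  for (int n = 0; n < N; ++n) {
    arma::mat P(pm.begin() + (keep_patches ? static_cast<R_xlen_t>(n) * prows * pcols : 0),
                prows, pcols, false, true);
    im2col(x.begin() + static_cast<R_xlen_t>(n) * H * W * C,
           H, W, C, kh, kw, stride, pad, Ho, Wo, P);
    arma::mat Y(y.begin() + static_cast<R_xlen_t>(n) * Ho * Wo * Co, prows, Co, false, true);
    Y = P * Wm;
    Y.each_row() += arma::rowvec(const_cast<double *>(bias.begin()), Co, false, true);
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, Co, N);
  return List::create(_["y"] = y,
                      _["patches"] = keep_patches ? SEXP(pm) : R_NilValue);
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd(NumericVector x, IntegerVector xdim,
                NumericVector w, IntegerVector wdim,
                NumericVector gy, int stride, int pad) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int kh = wdim[0], kw = wdim[1], Ci = wdim[2], Co = wdim[3];
  const int Ho = out_extent(H, kh, pad, stride);
  const int Wo = out_extent(W, kw, pad, stride);
  const arma::uword prows = static_cast<arma::uword>(Ho) * Wo;
  const arma::uword pcols = static_cast<arma::uword>(kh) * kw * Ci;
  NumericVector gx(static_cast<R_xlen_t>(H) * W * C * N), gw(w.size()), gb(Co);
  const arma::mat Wm(const_cast<double *>(w.begin()), pcols, Co, false, true);
  arma::mat GW(gw.begin(), pcols, Co, false, true);
  arma::rowvec GB(gb.begin(), Co, false, true);
  arma::mat P(prows, pcols);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + static_cast<R_xlen_t>(n) * H * W * C,
           H, W, C, kh, kw, stride, pad, Ho, Wo, P);
    const arma::mat GY(const_cast<double *>(gy.begin()) + static_cast<R_xlen_t>(n) * Ho * Wo * Co,
                       prows, Co, false, true);
    GW += P.t() * GY;
    GB += arma::sum(GY, 0);
    arma::mat GP = GY * Wm.t();
    col2im_add(GP, H, W, C, kh, kw, stride, pad, Ho, Wo,
               gx.begin() + static_cast<R_xlen_t>(n) * H * W * C);
  }
  gx.attr("dim") = xdim;
  gw.attr("dim") = wdim;
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Felzenszwalb & Huttenlocher 1-D squared distance transform on a grid with
// sample step `t` (mm). f is INF except 0 at feature samples (or a previous
// pass's squared distances).
static void dt1d(const double *f, double *d, int n, double t, int *v, double *z) {
  // seed with the first finite parabola; infinite entries cannot minimize
  int first = 0;
  while (first < n && f[first] == DBL_MAX) ++first;
  if (first == n) {
    std::fill(d, d + n, DBL_MAX);
    return;
  }
  int k = 0;
  v[0] = first;
  z[0] = -DBL_MAX;
  z[1] = DBL_MAX;
  for (int q = first + 1; q < n; ++q) {
    if (f[q] == DBL_MAX) continue;
    double s = ((f[q] + q * (double)q * t * t) - (f[v[k]] + v[k] * (double)v[k] * t * t)) /
               (2.0 * t * (q - v[k]));
    while (s <= z[k]) {
      --k;
      s = ((f[q] + q * (double)q * t * t) - (f[v[k]] + v[k] * (double)v[k] * t * t)) /
          (2.0 * t * (q - v[k]));
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = DBL_MAX;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q * t) ++k;
    const double dq = (q - v[k]) * t;
    d[q] = dq * dq + f[v[k]];
  }
}

// Anisotropic squared Euclidean distance transform of a 3-D binary mask
// (dim (Z, Y, X), column-major); distance from each voxel center to the
// nearest foreground voxel center, in mm given spacing (dz, dy, dx).
// [[Rcpp::export(name = ".edt3d_sq")]]
NumericVector edt3d_sq(LogicalVector mask, IntegerVector mdim, NumericVector spacing) {
  const int Z = mdim[0], Y = mdim[1], X = mdim[2];
  const double dz = spacing[0], dy = spacing[1], dx = spacing[2];
  const R_xlen_t nvox = static_cast<R_xlen_t>(Z) * Y * X;
  std::vector<double> d(nvox);
  for (R_xlen_t i = 0; i < nvox; ++i) d[i] = mask[i] ? 0.0 : DBL_MAX;
  const int nmax = std::max(Z, std::max(Y, X));
  std::vector<double> f(nmax), out(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  // pass along Z (fastest axis)
  for (int x = 0; x < X; ++x)
    for (int y = 0; y < Y; ++y) {
      double *col = d.data() + (static_cast<R_xlen_t>(x) * Y + y) * Z;
      dt1d(col, out.data(), Z, dz, v.data(), z.data());
      std::copy(out.begin(), out.begin() + Z, col);
    }
  // pass along Y
  for (int x = 0; x < X; ++x)
    for (int zz = 0; zz < Z; ++zz) {
      for (int y = 0; y < Y; ++y) f[y] = d[zz + (static_cast<R_xlen_t>(x) * Y + y) * Z];
      dt1d(f.data(), out.data(), Y, dy, v.data(), z.data());
      for (int y = 0; y < Y; ++y) d[zz + (static_cast<R_xlen_t>(x) * Y + y) * Z] = out[y];
    }
  // pass along X
  for (int y = 0; y < Y; ++y)
    for (int zz = 0; zz < Z; ++zz) {
      for (int x = 0; x < X; ++x) f[x] = d[zz + (static_cast<R_xlen_t>(x) * Y + y) * Z];
      dt1d(f.data(), out.data(), X, dx, v.data(), z.data());
      for (int x = 0; x < X; ++x) d[zz + (static_cast<R_xlen_t>(x) * Y + y) * Z] = out[x];
    }
  NumericVector res(nvox);
  std::copy(d.begin(), d.end(), res.begin());
  res.attr("dim") = mdim;
  return res;
}
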