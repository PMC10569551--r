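// 3D convolution with "same" zero padding, implemented as a sum of
// per-kernel-offset GEMMs so the heavy lifting stays in BLAS.
//
// Activations are stored as (V, C, N) arrays with V = D*H*W voxels in
// (z, y, x) column-major order (z fastest); weights as a (k^3 * Cin, Cout)
// matrix whose row index is offset + k^3 * cin, matching an R array of
// dim c(k, k, k, Cin, Cout).
//
// The shifted-image gather/scatter exploits that for a fixed offset the
// source index is the destination index plus a constant, so whole z-columns
// move as contiguous segments (no per-voxel bounds checks).
#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// out[z,y,x] = src[z+dz, y+dy, x+dx] (zero outside), one channel
static void gather_shift(const double* src, double* out, int D, int H, int W,
                         int dz, int dy, int dx) {
  int z0 = std::max(0, -dz), z1 = std::min(D, D - dz);
  for (int x = 0; x < W; ++x) {
    int sx = x + dx;
    for (int y = 0; y < H; ++y) {
      int sy = y + dy;
      double* dst = out + ((size_t)x * H + y) * D;
      if (sx < 0 || sx >= W || sy < 0 || sy >= H || z1 <= z0) {
        std::memset(dst, 0, sizeof(double) * D);
        continue;
      }
      const double* s = src + ((size_t)sx * H + sy) * D + dz;
      if (z0 > 0) std::memset(dst, 0, sizeof(double) * z0);
      std::memcpy(dst + z0, s + z0, sizeof(double) * (z1 - z0));
      if (z1 < D) std::memset(dst + z1, 0, sizeof(double) * (D - z1));
    }
  }
}

// dst[z+dz, y+dy, x+dx] += val[z,y,x] (dropping out-of-range), one channel
static void scatter_shift_add(const double* val, double* dst, int D, int H,
                              int W, int dz, int dy, int dx) {
  int z0 = std::max(0, -dz), z1 = std::min(D, D - dz);
  for (int x = 0; x < W; ++x) {
    int sx = x + dx;
    if (sx < 0 || sx >= W) continue;
    for (int y = 0; y < H; ++y) {
      int sy = y + dy;
      if (sy < 0 || sy >= H) continue;
      const double* v = val + ((size_t)x * H + y) * D;
      double* d = dst + ((size_t)sx * H + sy) * D + dz;
      for (int z = z0; z < z1; ++z) d[z] += v[z];
    }
  }
}

// [[Rcpp::export]]
NumericVector conv3d_forward_cpp(NumericVector x, IntegerVector dims,
                                 NumericMatrix w, NumericVector bias, int k) {
  int D = dims[0], H = dims[1], W = dims[2];
  int V = D * H * W;
  int k3 = k * k * k;
  int Cin = w.nrow() / k3;
  int Cout = w.ncol();
  IntegerVector xd = x.attr("dim");
  int N = (xd.size() == 3) ? xd[2] : 1;
  if (xd[0] != V || xd[1] != Cin) stop("conv3d: input shape mismatch");

  NumericVector y(V * (size_t)Cout * N);
  y.attr("dim") = IntegerVector::create(V, Cout, N);
  int half = (k - 1) / 2;
  arma::mat Xs(V, Cin), Wo(Cin, Cout);
  for (int o = 0; o < k3; ++o) {
    int dz = o % k - half, dy = (o / k) % k - half, dx = o / (k * k) - half;
    for (int ci = 0; ci < Cin; ++ci)
      for (int co = 0; co < Cout; ++co)
        Wo(ci, co) = w(o + k3 * ci, co);
    for (int n = 0; n < N; ++n) {
      const double* xn = REAL(x) + (size_t)n * V * Cin;
      for (int c = 0; c < Cin; ++c)
        gather_shift(xn + (size_t)c * V, Xs.colptr(c), D, H, W, dz, dy, dx);
      arma::mat Yn(REAL(y) + (size_t)n * V * Cout, V, Cout, false, true);
      Yn += Xs * Wo;
    }
  }
  if (bias.size() == Cout) {
    for (int n = 0; n < N; ++n)
      for (int co = 0; co < Cout; ++co) {
        double b = bias[co];
        double* col = REAL(y) + (size_t)n * V * Cout + (size_t)co * V;
        for (int v = 0; v < V; ++v) col[v] += b;
      }
  }
  return y;
}

// [[Rcpp::export]]
List conv3d_backward_cpp(NumericVector x, IntegerVector dims,
                         NumericMatrix w, NumericVector dy, int k,
                         bool has_bias) {
  int D = dims[0], H = dims[1], W = dims[2];
  int V = D * H * W;
  int k3 = k * k * k;
  int Cin = w.nrow() / k3;
  int Cout = w.ncol();
  IntegerVector xd = x.attr("dim");
  int N = (xd.size() == 3) ? xd[2] : 1;

  NumericVector dx(x.size());
  dx.attr("dim") = xd;
  NumericMatrix dw(w.nrow(), Cout);
  NumericVector db(has_bias ? Cout : 0);

  int half = (k - 1) / 2;
  arma::mat Xs(V, Cin), Wo(Cin, Cout), dWo(Cin, Cout);
  for (int o = 0; o < k3; ++o) {
    int dz = o % k - half, dyy = (o / k) % k - half, dxx = o / (k * k) - half;
    for (int ci = 0; ci < Cin; ++ci)
      for (int co = 0; co < Cout; ++co)
        Wo(ci, co) = w(o + k3 * ci, co);
    dWo.zeros();
    for (int n = 0; n < N; ++n) {
      const double* xn = REAL(x) + (size_t)n * V * Cin;
      for (int c = 0; c < Cin; ++c)
        gather_shift(xn + (size_t)c * V, Xs.colptr(c), D, H, W, dz, dyy, dxx);
      arma::mat dYn(REAL(dy) + (size_t)n * V * Cout, V, Cout, false, true);
      dWo += Xs.t() * dYn;
      arma::mat dXs = dYn * Wo.t();           // V x Cin
      double* dxn = REAL(dx) + (size_t)n * V * Cin;
      for (int c = 0; c < Cin; ++c)
        scatter_shift_add(dXs.colptr(c), dxn + (size_t)c * V, D, H, W,
                          dz, dyy, dxx);
    }
    for (int ci = 0; ci < Cin; ++ci)
      for (int co = 0; co < Cout; ++co)
        dw(o + k3 * ci, co) = dWo(ci, co);
  }
  if (has_bias) {
    for (int n = 0; n < N; ++n)
      for (int co = 0; co < Cout; ++co) {
        const double* col = REAL(dy) + (size_t)n * V * Cout + (size_t)co * V;
        double s = 0.0;
        for (int v = 0; v < V; ++v) s += col[v];
        db[co] += s;
      }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}
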