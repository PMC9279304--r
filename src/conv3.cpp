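#include <Rcpp.h>
#include <R_ext/BLAS.h>
#include <vector>
using namespace Rcpp;

// Fused 3x3x3 convolution (same padding) on V x C feature matrices via
// im2col + BLAS dgemm, with a reused scratch buffer to avoid per-call
// allocation. Layout: V = nx*ny*nz voxels, x fastest.

static std::vector<double>& col_buffer() {
  static std::vector<double> buf;
  return buf;
}

static void im2col_fill(const double* src, int nx, int ny, int nz, int C,
                        double* cols) {
  const int V = nx * ny * nz;
  const int K3 = 27;
  for (int c = 0; c < C; ++c) {
    const double* s = src + (size_t)V * c;
    int t = 0;
    for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
    for (int dx = -1; dx <= 1; ++dx, ++t) {
      double* d = cols + (size_t)V * (c * K3 + t);
      for (int z = 0; z < nz; ++z) {
        int zs = z + dz;
        for (int y = 0; y < ny; ++y) {
          int ys = y + dy;
          double* drow = d + (size_t)nx * (y + (size_t)ny * z);
          if (zs < 0 || zs >= nz || ys < 0 || ys >= ny) {
            std::fill(drow, drow + nx, 0.0);
            continue;
          }
          const double* srow = s + (size_t)nx * (ys + (size_t)ny * zs);
          int x0 = std::max(0, -dx), x1 = std::min(nx, nx - dx);
          for (int x = 0; x < x0; ++x) drow[x] = 0.0;
          for (int x = x0; x < x1; ++x) drow[x] = srow[x + dx];
          for (int x = x1; x < nx; ++x) drow[x] = 0.0;
        }
      }
    }
  }
}

static void col2im_acc(const double* cols, int nx, int ny, int nz, int C,
                       double* dst) {
  const int V = nx * ny * nz;
  const int K3 = 27;
  for (int c = 0; c < C; ++c) {
    double* d = dst + (size_t)V * c;
    int t = 0;
    for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
    for (int dx = -1; dx <= 1; ++dx, ++t) {
      const double* s = cols + (size_t)V * (c * K3 + t);
      for (int z = 0; z < nz; ++z) {
        int zs = z + dz;
        if (zs < 0 || zs >= nz) continue;
        for (int y = 0; y < ny; ++y) {
          int ys = y + dy;
          if (ys < 0 || ys >= ny) continue;
          const double* srow = s + (size_t)nx * (y + (size_t)ny * z);
          double* drow = d + (size_t)nx * (ys + (size_t)ny * zs);
          int x0 = std::max(0, -dx), x1 = std::min(nx, nx - dx);
          for (int x = x0; x < x1; ++x) drow[x + dx] += srow[x];
        }
      }
    }
  }
}

static void dgemm_(char ta, char tb, int m, int n, int k, double alpha,
                   const double* A, int lda, const double* B, int ldb,
                   double beta, double* Cm, int ldc) {
  F77_CALL(dgemm)(&ta, &tb, &m, &n, &k, &alpha, A, &lda, B, &ldb, &beta,
                  Cm, &ldc FCONE FCONE);
}

// [[Rcpp::export]]
NumericMatrix conv3_fwd_cpp(const NumericMatrix& x, IntegerVector dims,
                            const NumericMatrix& W, NumericVector b) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int V = nx * ny * nz, C = x.ncol(), Cout = W.ncol();
  const int K = C * 27;
  if (W.nrow() != K) stop("weight rows != C*27");
  std::vector<double>& cols = col_buffer();
  cols.resize((size_t)V * K);
  im2col_fill(REAL(x), nx, ny, nz, C, cols.data());
  NumericMatrix y(V, Cout);
  dgemm_('N', 'N', V, Cout, K, 1.0, cols.data(), V, REAL(W), K, 0.0, REAL(y), V);
  double* yp = REAL(y);
  for (int c = 0; c < Cout; ++c) {
    double bc = b[c];
    double* col = yp + (size_t)V * c;
    for (int v = 0; v < V; ++v) col[v] += bc;
  }
  return y;
}

// [[Rcpp::export]]
List conv3_bwd_cpp(const NumericMatrix& dy, const NumericMatrix& x,
                   IntegerVector dims, const NumericMatrix& W) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int V = nx * ny * nz, C = x.ncol(), Cout = W.ncol();
  const int K = C * 27;
  std::vector<double>& cols = col_buffer();
  cols.resize((size_t)V * K);
  im2col_fill(REAL(x), nx, ny, nz, C, cols.data());
  NumericMatrix dW(K, Cout);
  dgemm_('T', 'N', K, Cout, V, 1.0, cols.data(), V, REAL(dy), V, 0.0, REAL(dW), K);
  NumericVector db(Cout);
  for (int c = 0; c < Cout; ++c) {
    const double* col = REAL(dy) + (size_t)V * c;
    double s = 0; for (int v = 0; v < V; ++v) s += col[v];
    db[c] = s;
  }
  // dcols = dy %*% t(W), reusing the scratch buffer, then scatter to dx
  dgemm_('N', 'T', V, K, Cout, 1.0, REAL(dy), V, REAL(W), K, 0.0, cols.data(), V);
  NumericMatrix dx(V, C);
  col2im_acc(cols.data(), nx, ny, nz, C, REAL(dx));
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// [[Rcpp::export]]
NumericVector row_max_cpp(const NumericMatrix& m) {
  const int n = m.nrow(), k = m.ncol();
  NumericVector out(n, R_NegInf);
  for (int c = 0; c < k; ++c) {
    const double* col = REAL(m) + (size_t)n * c;
    for (int i = 0; i < n; ++i) if (col[i] > out[i]) out[i] = col[i];
  }
  return out;
}

// y[v,c] = x[v,c] * m[c] + a[c]  (fused per-column scale and shift)
// [[Rcpp::export]]
NumericMatrix scale_shift_cols_cpp(const NumericMatrix& x, NumericVector m,
                                   NumericVector a) {
  const int V = x.nrow(), C = x.ncol();
  NumericMatrix y(V, C);
  for (int c = 0; c < C; ++c) {
    const double* xc = REAL(x) + (size_t)V * c;
    double* yc = REAL(y) + (size_t)V * c;
    const double mc = m[c], ac = a[c];
    for (int v = 0; v < V; ++v) yc[v] = xc[v] * mc + ac;
  }
  return y;
}

// y[v,c] = x[v,c] + s[c] * z[v,c]  (per-column axpy)
// [[Rcpp::export]]
NumericMatrix add_scaled_cols_cpp(const NumericMatrix& x, NumericVector s,
                                  const NumericMatrix& z) {
  const int V = x.nrow(), C = x.ncol();
  NumericMatrix y(V, C);
  for (int c = 0; c < C; ++c) {
    const double* xc = REAL(x) + (size_t)V * c;
    const double* zc = REAL(z) + (size_t)V * c;
    double* yc = REAL(y) + (size_t)V * c;
    const double sc = s[c];
    for (int v = 0; v < V; ++v) yc[v] = xc[v] + sc * zc[v];
  }
  return y;
}
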