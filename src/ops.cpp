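#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// Feature maps are stored as V x C matrices (V = nx*ny*nz voxels, column-major
// spatial order: x fastest, then y, then z), so convolution becomes
// im2col + GEMM, with the GEMM done in R via %*% (BLAS).

static inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// [[Rcpp::export]]
NumericMatrix im2col3(const NumericMatrix& feat, IntegerVector dims, int k) {
  // feat: V x C; dims = (nx, ny, nz); k = kernel size (odd); zero padding k/2
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int C = feat.ncol();
  const int V = nx * ny * nz;
  const int r = k / 2, K3 = k * k * k;
  NumericMatrix out(V, C * K3);
  for (int c = 0; c < C; ++c) {
    const double* src = &feat(0, c);
    int t = 0;
    for (int dz = -r; dz <= r; ++dz)
    for (int dy = -r; dy <= r; ++dy)
    for (int dx = -r; dx <= r; ++dx, ++t) {
      double* dst = &out(0, c * K3 + t);
      for (int z = 0; z < nz; ++z) {
        int zs = z + dz;
        bool zok = (zs >= 0 && zs < nz);
        for (int y = 0; y < ny; ++y) {
          int ys = y + dy;
          bool yok = zok && (ys >= 0 && ys < ny);
          int base = nx * (y + ny * z);
          if (!yok) continue; // zero padding: out already zero
          int sbase = nx * (ys + ny * zs);
          int x0 = std::max(0, -dx), x1 = std::min(nx, nx - dx);
          for (int x = x0; x < x1; ++x)
            dst[base + x] = src[sbase + x + dx];
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix col2im3(const NumericMatrix& cols, IntegerVector dims, int k, int C) {
  // adjoint of im2col3: cols V x (C*k^3) -> V x C
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int V = nx * ny * nz;
  const int r = k / 2, K3 = k * k * k;
  NumericMatrix out(V, C);
  for (int c = 0; c < C; ++c) {
    double* dst = &out(0, c);
    int t = 0;
    for (int dz = -r; dz <= r; ++dz)
    for (int dy = -r; dy <= r; ++dy)
    for (int dx = -r; dx <= r; ++dx, ++t) {
      const double* src = &cols(0, c * K3 + t);
      for (int z = 0; z < nz; ++z) {
        int zs = z + dz;
        if (zs < 0 || zs >= nz) continue;
        for (int y = 0; y < ny; ++y) {
          int ys = y + dy;
          if (ys < 0 || ys >= ny) continue;
          int base = nx * (y + ny * z);
          int sbase = nx * (ys + ny * zs);
          int x0 = std::max(0, -dx), x1 = std::min(nx, nx - dx);
          for (int x = x0; x < x1; ++x)
            dst[sbase + x + dx] += src[base + x];
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
List maxpool3(const NumericMatrix& feat, IntegerVector dims) {
  // 2x2x2 max pooling, stride 2; dims must be even. Returns pooled V' x C and
  // 1-based argmax indices into the input rows for backprop.
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int C = feat.ncol();
  const int ox = nx / 2, oy = ny / 2, oz = nz / 2;
  const int OV = ox * oy * oz;
  NumericMatrix out(OV, C);
  IntegerMatrix arg(OV, C);
  for (int c = 0; c < C; ++c) {
    const double* src = &feat(0, c);
    for (int z = 0; z < oz; ++z)
    for (int y = 0; y < oy; ++y)
    for (int x = 0; x < ox; ++x) {
      double best = -1e300; int bi = -1;
      for (int dz = 0; dz < 2; ++dz)
      for (int dy = 0; dy < 2; ++dy)
      for (int dx = 0; dx < 2; ++dx) {
        int i = idx3(2 * x + dx, 2 * y + dy, 2 * z + dz, nx, ny);
        if (src[i] > best) { best = src[i]; bi = i; }
      }
      int o = idx3(x, y, z, ox, oy);
      out(o, c) = best;
      arg(o, c) = bi + 1;
    }
  }
  return List::create(_["out"] = out, _["argmax"] = arg,
                      _["dims"] = IntegerVector::create(ox, oy, oz));
}

// [[Rcpp::export]]
NumericMatrix upsample2_nn(const NumericMatrix& feat, IntegerVector dims) {
  // nearest-neighbour 2x upsampling of a V x C feature matrix
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int C = feat.ncol();
  const int ox = nx * 2, oy = ny * 2, oz = nz * 2;
  NumericMatrix out(ox * oy * oz, C);
  for (int c = 0; c < C; ++c) {
    const double* src = &feat(0, c);
    double* dst = &out(0, c);
    for (int z = 0; z < oz; ++z)
    for (int y = 0; y < oy; ++y) {
      int sbase = nx * ((y / 2) + ny * (z / 2));
      int base = ox * (y + oy * z);
      for (int x = 0; x < ox; ++x)
        dst[base + x] = src[sbase + x / 2];
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix upsample2_nn_bwd(const NumericMatrix& grad, IntegerVector outdims) {
  // adjoint of upsample2_nn; grad has dims 2*outdims
  const int ox = outdims[0], oy = outdims[1], oz = outdims[2];
  const int nx = ox * 2, ny = oy * 2, nz = oz * 2;
  const int C = grad.ncol();
  NumericMatrix out(ox * oy * oz, C);
  for (int c = 0; c < C; ++c) {
    const double* src = &grad(0, c);
    double* dst = &out(0, c);
    for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      int dbase = ox * ((y / 2) + oy * (z / 2));
      int base = nx * (y + ny * z);
      for (int x = 0; x < nx; ++x)
        dst[dbase + x / 2] += src[base + x];
    }
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector label_components3(const LogicalVector& mask, IntegerVector dims,
                                int connectivity) {
  // connected components of a 3D mask; connectivity 6 or 26. Returns labels
  // (0 = background), components numbered from 1 in discovery order.
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int V = nx * ny * nz;
  IntegerVector lab(V, 0);
  std::vector<std::array<int, 3>> offs;
  for (int dz = -1; dz <= 1; ++dz)
  for (int dy = -1; dy <= 1; ++dy)
  for (int dx = -1; dx <= 1; ++dx) {
    if (dx == 0 && dy == 0 && dz == 0) continue;
    int man = std::abs(dx) + std::abs(dy) + std::abs(dz);
    if (connectivity == 6 && man > 1) continue;
    offs.push_back({dx, dy, dz});
  }
  int cur = 0;
  std::vector<int> stack;
  for (int seed = 0; seed < V; ++seed) {
    if (!mask[seed] || lab[seed] != 0) continue;
    ++cur;
    lab[seed] = cur;
    stack.push_back(seed);
    while (!stack.empty()) {
      int i = stack.back(); stack.pop_back();
      int x = i % nx, y = (i / nx) % ny, z = i / (nx * ny);
      for (auto& o : offs) {
        int xx = x + o[0], yy = y + o[1], zz = z + o[2];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
        int j = idx3(xx, yy, zz, nx, ny);
        if (mask[j] && lab[j] == 0) { lab[j] = cur; stack.push_back(j); }
      }
    }
  }
  lab.attr("n_components") = cur;
  return lab;
}

// [[Rcpp::export]]
IntegerVector label_components2(const LogicalVector& mask, IntegerVector dims,
                                int connectivity) {
  // 2D components (in-plane); connectivity 4 or 8
  const int nx = dims[0], ny = dims[1];
  const int V = nx * ny;
  IntegerVector lab(V, 0);
  std::vector<std::array<int, 2>> offs;
  for (int dy = -1; dy <= 1; ++dy)
  for (int dx = -1; dx <= 1; ++dx) {
    if (dx == 0 && dy == 0) continue;
    if (connectivity == 4 && std::abs(dx) + std::abs(dy) > 1) continue;
    offs.push_back({dx, dy});
  }
  int cur = 0;
  std::vector<int> stack;
  for (int seed = 0; seed < V; ++seed) {
    if (!mask[seed] || lab[seed] != 0) continue;
    ++cur;
    lab[seed] = cur;
    stack.push_back(seed);
    while (!stack.empty()) {
      int i = stack.back(); stack.pop_back();
      int x = i % nx, y = i / nx;
      for (auto& o : offs) {
        int xx = x + o[0], yy = y + o[1];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny) continue;
        int j = xx + nx * yy;
        if (mask[j] && lab[j] == 0) { lab[j] = cur; stack.push_back(j); }
      }
    }
  }
  lab.attr("n_components") = cur;
  return lab;
}
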