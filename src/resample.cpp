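// Geometric kernels: affine resampling of 3D grids (nearest / trilinear /
// Keys cubic), the correlation-ratio similarity metric used by the
// registration optimizer, block-mean pyramid downsampling, and a 6-connected
// component counter used by the phantom invariants.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double sample_nearest(const double* v, int nx, int ny, int nz,
                                    double x, double y, double z) {
  int i = (int)std::lround(x), j = (int)std::lround(y), k = (int)std::lround(z);
  if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return 0.0;
  return v[(size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * (size_t)k)];
}

static inline double at0(const double* v, int nx, int ny, int nz, int i, int j, int k) {
  if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return 0.0;
  return v[(size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * (size_t)k)];
}

static inline double sample_linear(const double* v, int nx, int ny, int nz,
                                   double x, double y, double z) {
  // out-of-field treated as 0
  if (x <= -1.0 || y <= -1.0 || z <= -1.0 || x >= nx || y >= ny || z >= nz) return 0.0;
  int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
  double fx = x - i0, fy = y - j0, fz = z - k0;
  double acc = 0.0;
  for (int dk = 0; dk <= 1; ++dk) {
    double wz = dk ? fz : 1.0 - fz;
    if (wz == 0.0) continue;
    for (int dj = 0; dj <= 1; ++dj) {
      double wy = dj ? fy : 1.0 - fy;
      if (wy == 0.0) continue;
      for (int di = 0; di <= 1; ++di) {
        double wx = di ? fx : 1.0 - fx;
        if (wx == 0.0) continue;
        acc += wx * wy * wz * at0(v, nx, ny, nz, i0 + di, j0 + dj, k0 + dk);
      }
    }
  }
  return acc;
}

// Keys cubic convolution kernel (a = -0.5), interpolating.
static inline double keys_w(double t) {
  t = std::fabs(t);
  if (t < 1.0) return ((1.5 * t - 2.5) * t) * t + 1.0;
  if (t < 2.0) return (((-0.5 * t) + 2.5) * t - 4.0) * t + 2.0;
  return 0.0;
}

static inline double sample_cubic(const double* v, int nx, int ny, int nz,
                                  double x, double y, double z) {
  if (x <= -2.0 || y <= -2.0 || z <= -2.0 || x >= nx + 1 || y >= ny + 1 || z >= nz + 1)
    return 0.0;
  int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
  double wx[4], wy[4], wz[4];
  for (int d = -1; d <= 2; ++d) {
    wx[d + 1] = keys_w(x - (i0 + d));
    wy[d + 1] = keys_w(y - (j0 + d));
    wz[d + 1] = keys_w(z - (k0 + d));
  }
  double acc = 0.0;
  for (int dk = 0; dk < 4; ++dk) {
    if (wz[dk] == 0.0) continue;
    double accj = 0.0;
    for (int dj = 0; dj < 4; ++dj) {
      if (wy[dj] == 0.0) continue;
      double acci = 0.0;
      for (int di = 0; di < 4; ++di)
        acci += wx[di] * at0(v, nx, ny, nz, i0 - 1 + di, j0 - 1 + dj, k0 - 1 + dk);
      accj += wy[dj] * acci;
    }
    acc += wz[dk] * accj;
  }
  return acc;
}

// Resample a source grid onto a target grid. M is the 4x4 matrix taking
// 0-based target voxel indices to 0-based source voxel coordinates.
// interp: 0 = nearest, 1 = trilinear, 3 = cubic spline (Keys).
// [[Rcpp::export]]
NumericVector cpp_resample(NumericVector src, IntegerVector src_dim,
                           IntegerVector tgt_dim, NumericMatrix M, int interp) {
  const int nx = src_dim[0], ny = src_dim[1], nz = src_dim[2];
  const int tx = tgt_dim[0], ty = tgt_dim[1], tz = tgt_dim[2];
  const double* v = src.begin();
  NumericVector out((R_xlen_t)tx * ty * tz);
  double* o = out.begin();
  const double m00 = M(0,0), m01 = M(0,1), m02 = M(0,2), m03 = M(0,3);
  const double m10 = M(1,0), m11 = M(1,1), m12 = M(1,2), m13 = M(1,3);
  const double m20 = M(2,0), m21 = M(2,1), m22 = M(2,2), m23 = M(2,3);
  size_t idx = 0;
  for (int k = 0; k < tz; ++k) {
    for (int j = 0; j < ty; ++j) {
      double bx = m01 * j + m02 * k + m03;
      double by = m11 * j + m12 * k + m13;
      double bz = m21 * j + m22 * k + m23;
      for (int i = 0; i < tx; ++i, ++idx) {
        double x = m00 * i + bx, y = m10 * i + by, z = m20 * i + bz;
        double val;
        if (interp == 0)      val = sample_nearest(v, nx, ny, nz, x, y, z);
        else if (interp == 1) val = sample_linear(v, nx, ny, nz, x, y, z);
        else                  val = sample_cubic(v, nx, ny, nz, x, y, z);
        o[idx] = val;
      }
    }
  }
  out.attr("dim") = tgt_dim;
  return out;
}

// Correlation-ratio cost 1 - eta^2(moving | fixed-intensity bin), evaluated at
// a precomputed list of fixed-grid voxels. vox: n x 3 matrix of 0-based fixed
// voxel indices; bin: length-n 0-based bin assignment of the fixed intensity;
// w: per-voxel weights. M maps fixed voxel indices to moving voxel coords.
// The ratio is computed over the voxels that land inside the moving field of
// view, and the out-of-field weight fraction is added to the cost: a constant
// out-of-field background would otherwise score a perfect correlation ratio,
// rewarding transforms that slide the image away entirely.
// [[Rcpp::export]]
double cpp_cr_cost(NumericVector mov, IntegerVector mov_dim, IntegerMatrix vox,
                   IntegerVector bin, NumericVector w, int nbins,
                   NumericMatrix M) {
  const int nx = mov_dim[0], ny = mov_dim[1], nz = mov_dim[2];
  const double* v = mov.begin();
  const int n = vox.nrow();
  std::vector<double> W(nbins, 0.0), S(nbins, 0.0), S2(nbins, 0.0);
  const double m00 = M(0,0), m01 = M(0,1), m02 = M(0,2), m03 = M(0,3);
  const double m10 = M(1,0), m11 = M(1,1), m12 = M(1,2), m13 = M(1,3);
  const double m20 = M(2,0), m21 = M(2,1), m22 = M(2,2), m23 = M(2,3);
  double w_all = 0.0, w_in = 0.0;
  for (int r = 0; r < n; ++r) {
    double wi = w[r];
    if (wi <= 0.0) continue;
    w_all += wi;
    double i = vox(r, 0), j = vox(r, 1), k = vox(r, 2);
    double x = m00 * i + m01 * j + m02 * k + m03;
    double y = m10 * i + m11 * j + m12 * k + m13;
    double z = m20 * i + m21 * j + m22 * k + m23;
    if (x < 0.0 || y < 0.0 || z < 0.0 ||
        x > nx - 1.0 || y > ny - 1.0 || z > nz - 1.0) continue;
    w_in += wi;
    double s = sample_linear(v, nx, ny, nz, x, y, z);
    int b = bin[r];
    W[b] += wi; S[b] += wi * s; S2[b] += wi * s * s;
  }
  if (w_all <= 0.0) return 1.0;
  const double out_frac = 1.0 - w_in / w_all;
  if (w_in <= 0.05 * w_all) return 1.0 + out_frac;
  double Wt = 0.0, St = 0.0, S2t = 0.0, within = 0.0;
  for (int b = 0; b < nbins; ++b) {
    if (W[b] <= 0.0) continue;
    Wt += W[b]; St += S[b]; S2t += S2[b];
    within += S2[b] - S[b] * S[b] / W[b];
  }
  double total = S2t - St * St / Wt;
  double cost;
  if (total <= 1e-12) cost = 1.0;
  else {
    cost = within / total;
    if (cost < 0.0) cost = 0.0;
    if (cost > 1.0) cost = 1.0;
  }
  return cost + out_frac;
}

// Block-mean downsampling by an integer factor along each axis (truncating
// incomplete blocks), used for the multi-resolution registration pyramid.
// [[Rcpp::export]]
NumericVector cpp_block_mean(NumericVector src, IntegerVector dim, int f) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int ox = nx / f, oy = ny / f, oz = nz / f;
  const double* v = src.begin();
  NumericVector out((R_xlen_t)ox * oy * oz);
  double* o = out.begin();
  const double inv = 1.0 / (double)(f * f * f);
  for (int k = 0; k < oz; ++k)
    for (int j = 0; j < oy; ++j)
      for (int i = 0; i < ox; ++i) {
        double acc = 0.0;
        for (int dk = 0; dk < f; ++dk)
          for (int dj = 0; dj < f; ++dj)
            for (int di = 0; di < f; ++di)
              acc += v[(size_t)(i * f + di) +
                       (size_t)nx * ((size_t)(j * f + dj) + (size_t)ny * (size_t)(k * f + dk))];
        o[(size_t)i + (size_t)ox * ((size_t)j + (size_t)oy * (size_t)k)] = acc * inv;
      }
  out.attr("dim") = IntegerVector::create(ox, oy, oz);
  return out;
}

// Number of 6-connected foreground components of a binary 3D mask.
// [[Rcpp::export]]
int cpp_n_components6(IntegerVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const size_t n = (size_t)nx * ny * nz;
  std::vector<char> seen(n, 0);
  const int* m = mask.begin();
  int ncomp = 0;
  std::vector<size_t> stack;
  const int dxs[6] = {1,-1,0,0,0,0}, dys[6] = {0,0,1,-1,0,0}, dzs[6] = {0,0,0,0,1,-1};
  for (size_t s = 0; s < n; ++s) {
    if (!m[s] || seen[s]) continue;
    ++ncomp;
    stack.clear(); stack.push_back(s); seen[s] = 1;
    while (!stack.empty()) {
      size_t cur = stack.back(); stack.pop_back();
      int i = (int)(cur % nx), j = (int)((cur / nx) % ny), k = (int)(cur / ((size_t)nx * ny));
      for (int d = 0; d < 6; ++d) {
        int ii = i + dxs[d], jj = j + dys[d], kk = k + dzs[d];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
        size_t t = (size_t)ii + (size_t)nx * ((size_t)jj + (size_t)ny * (size_t)kk);
        if (m[t] && !seen[t]) { seen[t] = 1; stack.push_back(t); }
      }
    }
  }
  return ncomp;
}
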