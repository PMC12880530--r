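#include <Rcpp.h>
#include <cmath>
#include <limits>
#include <vector>
using namespace Rcpp;

// Arrays are R-style column-major with dim = (n1, n2, n3); for volumes the
// package convention is depth-major (z, y, x). All ops are isotropic in
// voxel units; callers convert to micrometres.

static inline R_xlen_t idx3(int i, int j, int k, int n1, int n2) {
  return (R_xlen_t)i + (R_xlen_t)n1 * ((R_xlen_t)j + (R_xlen_t)n2 * k);
}

// 1D squared distance transform (Felzenszwalb & Huttenlocher)
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; q++) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { k--; } else break;
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Euclidean distance (voxels) from each foreground voxel (vol != 0) to the
// nearest background voxel. Background voxels get 0.
// [[Rcpp::export]]
NumericVector cpp_edt3d(NumericVector vol, IntegerVector dim) {
  int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  const double INF = 1e20;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; i++) out[i] = vol[i] != 0 ? INF : 0.0;
  std::vector<double> f, d;
  // axis 1
  f.resize(n1); d.resize(n1);
  for (int k = 0; k < n3; k++)
    for (int j = 0; j < n2; j++) {
      for (int i = 0; i < n1; i++) f[i] = out[idx3(i, j, k, n1, n2)];
      dt1d(f, d, n1);
      for (int i = 0; i < n1; i++) out[idx3(i, j, k, n1, n2)] = d[i];
    }
  // axis 2
  f.resize(n2); d.resize(n2);
  for (int k = 0; k < n3; k++)
    for (int i = 0; i < n1; i++) {
      for (int j = 0; j < n2; j++) f[j] = out[idx3(i, j, k, n1, n2)];
      dt1d(f, d, n2);
      for (int j = 0; j < n2; j++) out[idx3(i, j, k, n1, n2)] = d[j];
    }
  // axis 3
  f.resize(n3); d.resize(n3);
  for (int j = 0; j < n2; j++)
    for (int i = 0; i < n1; i++) {
      for (int k = 0; k < n3; k++) f[k] = out[idx3(i, j, k, n1, n2)];
      dt1d(f, d, n3);
      for (int k = 0; k < n3; k++) out[idx3(i, j, k, n1, n2)] = d[k];
    }
  for (R_xlen_t i = 0; i < n; i++) out[i] = std::sqrt(out[i]);
  out.attr("dim") = dim;
  return out;
}

static void blur_axis(std::vector<double>& a, int n1, int n2, int n3,
                      int axis, double sigma) {
  if (sigma <= 0) return;
  int r = (int)std::ceil(3.0 * sigma);
  std::vector<double> ker(2 * r + 1);
  for (int t = -r; t <= r; t++)
    ker[t + r] = std::exp(-0.5 * t * t / (sigma * sigma));
  int len = axis == 0 ? n1 : (axis == 1 ? n2 : n3);
  // stride along the axis and extents of the two orthogonal axes
  R_xlen_t stride = axis == 0 ? 1
                  : (axis == 1 ? (R_xlen_t)n1 : (R_xlen_t)n1 * n2);
  int u1 = axis == 0 ? n2 : n1;
  int u2 = axis == 2 ? n2 : n3;
  std::vector<double> line(len), res(len);
  for (int q2 = 0; q2 < u2; q2++)
    for (int q1 = 0; q1 < u1; q1++) {
      R_xlen_t base;
      if (axis == 0)      base = idx3(0, q1, q2, n1, n2);
      else if (axis == 1) base = idx3(q1, 0, q2, n1, n2);
      else                base = idx3(q1, q2, 0, n1, n2);
      for (int t = 0; t < len; t++) line[t] = a[base + stride * t];
      for (int t = 0; t < len; t++) {
        double s = 0, w = 0;
        int lo = std::max(0, t - r), hi = std::min(len - 1, t + r);
        for (int u = lo; u <= hi; u++) {
          double kk = ker[u - t + r];
          s += kk * line[u];
          w += kk;
        }
        res[t] = s / w;
      }
      for (int t = 0; t < len; t++) a[base + stride * t] = res[t];
    }
}

// Separable Gaussian blur, sigma in voxels; edge-renormalized kernel.
// [[Rcpp::export]]
NumericVector cpp_gauss3d(NumericVector vol, IntegerVector dim,
                          double sigma) {
  int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  std::vector<double> a(n);
  for (R_xlen_t i = 0; i < n; i++) a[i] = vol[i];
  for (int axis = 0; axis < 3; axis++) blur_axis(a, n1, n2, n3, axis, sigma);
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; i++) out[i] = a[i];
  out.attr("dim") = dim;
  return out;
}

// Paint solid spheres: vol[v] = max(vol[v], value) for voxels whose center
// lies within radius of the sphere center. Centers/radii in continuous
// 0-based voxel coordinates (voxel center at integer coordinates).
// [[Rcpp::export]]
void cpp_stamp_spheres(NumericVector vol, IntegerVector dim,
                       NumericMatrix centers, NumericVector radii,
                       double value) {
  int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  for (int s = 0; s < centers.nrow(); s++) {
    double cz = centers(s, 0), cy = centers(s, 1), cx = centers(s, 2);
    double r = radii[s];
    double r2 = r * r;
    int i0 = std::max(0, (int)std::floor(cz - r));
    int i1 = std::min(n1 - 1, (int)std::ceil(cz + r));
    int j0 = std::max(0, (int)std::floor(cy - r));
    int j1 = std::min(n2 - 1, (int)std::ceil(cy + r));
    int k0 = std::max(0, (int)std::floor(cx - r));
    int k1 = std::min(n3 - 1, (int)std::ceil(cx + r));
    for (int k = k0; k <= k1; k++)
      for (int j = j0; j <= j1; j++)
        for (int i = i0; i <= i1; i++) {
          double dz = i - cz, dy = j - cy, dx = k - cx;
          if (dz * dz + dy * dy + dx * dx <= r2) {
            R_xlen_t id = idx3(i, j, k, n1, n2);
            if (vol[id] < value) vol[id] = value;
          }
        }
  }
}

// Additive Gaussian blobs: vol += amp * exp(-d^2 / (2 sigma^2)) within 3
// sigma. Coordinates as in cpp_stamp_spheres.
// [[Rcpp::export]]
void cpp_stamp_gaussians(NumericVector vol, IntegerVector dim,
                         NumericMatrix centers, NumericVector sigma,
                         NumericVector amp) {
  int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  for (int s = 0; s < centers.nrow(); s++) {
    double cz = centers(s, 0), cy = centers(s, 1), cx = centers(s, 2);
    double sg = sigma[s], A = amp[s];
    double r = 3.0 * sg;
    int i0 = std::max(0, (int)std::floor(cz - r));
    int i1 = std::min(n1 - 1, (int)std::ceil(cz + r));
    int j0 = std::max(0, (int)std::floor(cy - r));
    int j1 = std::min(n2 - 1, (int)std::ceil(cy + r));
    int k0 = std::max(0, (int)std::floor(cx - r));
    int k1 = std::min(n3 - 1, (int)std::ceil(cx + r));
    for (int k = k0; k <= k1; k++)
      for (int j = j0; j <= j1; j++)
        for (int i = i0; i <= i1; i++) {
          double dz = i - cz, dy = j - cy, dx = k - cx;
          double d2 = dz * dz + dy * dy + dx * dx;
          if (d2 <= r * r)
            vol[idx3(i, j, k, n1, n2)] += A * std::exp(-0.5 * d2 / (sg * sg));
        }
  }
}

// Linear 1-based indices of voxels above threshold that are >= all of
// their 26 neighbors.
// [[Rcpp::export]]
IntegerVector cpp_local_maxima(NumericVector vol, IntegerVector dim,
                               double threshold) {
  int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  std::vector<int> hits;
  for (int k = 0; k < n3; k++)
    for (int j = 0; j < n2; j++)
      for (int i = 0; i < n1; i++) {
        double v = vol[idx3(i, j, k, n1, n2)];
        if (v <= threshold) continue;
        bool mx = true;
        for (int dk = -1; dk <= 1 && mx; dk++)
          for (int dj = -1; dj <= 1 && mx; dj++)
            for (int di = -1; di <= 1 && mx; di++) {
              if (!di && !dj && !dk) continue;
              int ii = i + di, jj = j + dj, kk = k + dk;
              if (ii < 0 || jj < 0 || kk < 0 || ii >= n1 || jj >= n2 ||
                  kk >= n3)
                continue;
              if (vol[idx3(ii, jj, kk, n1, n2)] > v) mx = false;
            }
        if (mx) hits.push_back(1 + (int)idx3(i, j, k, n1, n2));
      }
  return wrap(hits);
}

// Minimum distance from each point to the polyline of each group:
// segments given as start/end matrices (n x 3) with a 1-based group id.
// Returns an (npoints x ngroups) matrix.
// [[Rcpp::export]]
NumericMatrix cpp_min_dist_groups(NumericMatrix pts, NumericMatrix a,
                                  NumericMatrix b, IntegerVector group,
                                  int ngroups) {
  int np = pts.nrow(), ns = a.nrow();
  NumericMatrix out(np, ngroups);
  std::fill(out.begin(), out.end(), R_PosInf);
  for (int s = 0; s < ns; s++) {
    double ax = a(s, 0), ay = a(s, 1), az = a(s, 2);
    double dx = b(s, 0) - ax, dy = b(s, 1) - ay, dz = b(s, 2) - az;
    double L2 = dx * dx + dy * dy + dz * dz;
    int g = group[s] - 1;
    for (int p = 0; p < np; p++) {
      double px = pts(p, 0) - ax, py = pts(p, 1) - ay, pz = pts(p, 2) - az;
      double t = L2 > 0 ? (px * dx + py * dy + pz * dz) / L2 : 0.0;
      if (t < 0) t = 0;
      if (t > 1) t = 1;
      double ex = px - t * dx, ey = py - t * dy, ez = pz - t * dz;
      double d2 = ex * ex + ey * ey + ez * ez;
      if (d2 < out(p, g)) out(p, g) = d2;
    }
  }
  for (int i = 0; i < np * ngroups; i++) out[i] = std::sqrt(out[i]);
  return out;
}

// Paint a chain of finite cylinders (no end caps): voxels whose
// projection onto edge (a,b) lies within [0,1] and radial distance <= r.
// Coordinates as in cpp_stamp_spheres; radius per edge in voxels.
// [[Rcpp::export]]
void cpp_stamp_cylinders(NumericVector vol, IntegerVector dim,
                         NumericMatrix a, NumericMatrix b,
                         NumericVector radius, double value) {
  int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  for (int s = 0; s < a.nrow(); s++) {
    double az = a(s, 0), ay = a(s, 1), ax = a(s, 2);
    double dz = b(s, 0) - az, dy = b(s, 1) - ay, dx = b(s, 2) - ax;
    double L2 = dz * dz + dy * dy + dx * dx;
    if (L2 <= 0) continue;
    double r = radius[s], r2 = r * r;
    int i0 = std::max(0, (int)std::floor(std::min(az, b(s, 0)) - r));
    int i1 = std::min(n1 - 1, (int)std::ceil(std::max(az, b(s, 0)) + r));
    int j0 = std::max(0, (int)std::floor(std::min(ay, b(s, 1)) - r));
    int j1 = std::min(n2 - 1, (int)std::ceil(std::max(ay, b(s, 1)) + r));
    int k0 = std::max(0, (int)std::floor(std::min(ax, b(s, 2)) - r));
    int k1 = std::min(n3 - 1, (int)std::ceil(std::max(ax, b(s, 2)) + r));
    for (int k = k0; k <= k1; k++)
      for (int j = j0; j <= j1; j++)
        for (int i = i0; i <= i1; i++) {
          double vz = i - az, vy = j - ay, vx = k - ax;
          double t = (vz * dz + vy * dy + vx * dx) / L2;
          if (t < 0 || t > 1) continue;
          double ez = vz - t * dz, ey = vy - t * dy, ex = vx - t * dx;
          if (ez * ez + ey * ey + ex * ex <= r2) {
            R_xlen_t id = idx3(i, j, k, n1, n2);
            if (vol[id] < value) vol[id] = value;
          }
        }
  }
}

// Per point: minimum over edges of (point-to-segment distance - edge
// radius), i.e. signed distance to the nearest tube wall.
// [[Rcpp::export]]
NumericVector cpp_min_wall_dist(NumericMatrix pts, NumericMatrix a,
                                NumericMatrix b, NumericVector redge) {
  int np = pts.nrow(), ns = a.nrow();
  NumericVector out(np, R_PosInf);
  for (int s = 0; s < ns; s++) {
    double ax = a(s, 0), ay = a(s, 1), az = a(s, 2);
    double dx = b(s, 0) - ax, dy = b(s, 1) - ay, dz = b(s, 2) - az;
    double L2 = dx * dx + dy * dy + dz * dz;
    double r = redge[s];
    for (int p = 0; p < np; p++) {
      double px = pts(p, 0) - ax, py = pts(p, 1) - ay, pz = pts(p, 2) - az;
      double t = L2 > 0 ? (px * dx + py * dy + pz * dz) / L2 : 0.0;
      if (t < 0) t = 0;
      if (t > 1) t = 1;
      double ex = px - t * dx, ey = py - t * dy, ez = pz - t * dz;
      double d = std::sqrt(ex * ex + ey * ey + ez * ez) - r;
      if (d < out[p]) out[p] = d;
    }
  }
  return out;
}
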