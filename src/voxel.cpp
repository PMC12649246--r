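// Voxel-grid primitives: threshold-connected region growing, border-seeded
// hole filling, anisotropic Euclidean distance transforms, physical-radius
// erosion, separable Gaussian smoothing, Laplacian, and upwind level-set
// evolution. Grids are R arrays in column-major order, index = x + nx*(y+ny*z).
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

static inline int lin(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// Neighbour offsets for 6- or 26-connectivity.
static void neighbour_offsets(int connectivity,
                              std::vector<int> &dx, std::vector<int> &dy,
                              std::vector<int> &dz) {
  dx.clear(); dy.clear(); dz.clear();
  if (connectivity == 6) {
    const int ox[6] = {1,-1,0,0,0,0}, oy[6] = {0,0,1,-1,0,0},
              oz[6] = {0,0,0,0,1,-1};
    for (int i = 0; i < 6; ++i) { dx.push_back(ox[i]); dy.push_back(oy[i]); dz.push_back(oz[i]); }
  } else { // 26
    for (int a = -1; a <= 1; ++a)
      for (int b = -1; b <= 1; ++b)
        for (int c = -1; c <= 1; ++c) {
          if (a == 0 && b == 0 && c == 0) continue;
          dx.push_back(a); dy.push_back(b); dz.push_back(c);
        }
  }
}

// [[Rcpp::export]]
LogicalVector cpp_region_grow(NumericVector img, IntegerVector dim,
                              IntegerVector seed0, double lower, double upper,
                              int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector out(n, false);
  std::vector<int> dx, dy, dz;
  neighbour_offsets(connectivity, dx, dy, dz);
  std::vector<int> stack;
  const int s = lin(seed0[0], seed0[1], seed0[2], nx, ny);
  out[s] = true;
  stack.push_back(s);
  while (!stack.empty()) {
    const int cur = stack.back(); stack.pop_back();
    const int cz = cur / (nx * ny);
    const int rem = cur - cz * nx * ny;
    const int cy = rem / nx, cx = rem - cy * nx;
    for (size_t k = 0; k < dx.size(); ++k) {
      const int xx = cx + dx[k], yy = cy + dy[k], zz = cz + dz[k];
      if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) continue;
      const int idx = lin(xx, yy, zz, nx, ny);
      if (out[idx]) continue;
      const double v = img[idx];
      if (v >= lower && v <= upper) { out[idx] = true; stack.push_back(idx); }
    }
  }
  return out;
}

// Fill background cavities not connected (under bg_connectivity) to the grid
// border. Foreground voxels are never removed.
// [[Rcpp::export]]
LogicalVector cpp_fill_holes(LogicalVector mask, IntegerVector dim,
                             int bg_connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<char> outside(n, 0);
  std::vector<int> dx, dy, dz;
  neighbour_offsets(bg_connectivity, dx, dy, dz);
  std::vector<int> stack;
  // seed from every background border voxel
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        if (x != 0 && y != 0 && z != 0 && x != nx - 1 && y != ny - 1 && z != nz - 1)
          continue;
        const int idx = lin(x, y, z, nx, ny);
        if (!mask[idx] && !outside[idx]) { outside[idx] = 1; stack.push_back(idx); }
      }
  while (!stack.empty()) {
    const int cur = stack.back(); stack.pop_back();
    const int cz = cur / (nx * ny);
    const int rem = cur - cz * nx * ny;
    const int cy = rem / nx, cx = rem - cy * nx;
    for (size_t k = 0; k < dx.size(); ++k) {
      const int xx = cx + dx[k], yy = cy + dy[k], zz = cz + dz[k];
      if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) continue;
      const int idx = lin(xx, yy, zz, nx, ny);
      if (!mask[idx] && !outside[idx]) { outside[idx] = 1; stack.push_back(idx); }
    }
  }
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] || !outside[i];
  return out;
}

// 1-D squared-distance transform (Felzenszwalb & Huttenlocher) with sample
// spacing h; f holds squared distances, overwritten in place via d.
static void dt1d(std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &zb, int n, double h) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0; zb[0] = -INF; zb[1] = INF;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF) continue;
    if (k == 0 && f[v[0]] == INF) { v[0] = q; continue; }
    double s;
    while (true) {
      const double xq = q * h, xv = v[k] * h;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2 * xq - 2 * xv);
      if (s <= zb[k]) { --k; } else break;
    }
    ++k;
    v[k] = q; zb[k] = s; zb[k + 1] = INF;
  }
  if (f[v[0]] == INF) { // no sites on this scan line
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    const double xq = q * h;
    while (zb[k + 1] < xq) ++k;
    const double dx = xq - v[k] * h;
    d[q] = dx * dx + f[v[k]];
  }
}

// Squared Euclidean distance (mm^2) from every voxel centre to the nearest
// foreground voxel centre; Inf if the mask is empty.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector fg, IntegerVector dim,
                         NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double INF = std::numeric_limits<double>::infinity();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = fg[i] ? 0.0 : INF;
  const int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), zb(nmax + 1);
  std::vector<int> v(nmax);
  // x pass
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) f[x] = out[lin(x, y, z, nx, ny)];
      dt1d(f, d, v, zb, nx, spacing[0]);
      for (int x = 0; x < nx; ++x) out[lin(x, y, z, nx, ny)] = d[x];
    }
  // y pass
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) f[y] = out[lin(x, y, z, nx, ny)];
      dt1d(f, d, v, zb, ny, spacing[1]);
      for (int y = 0; y < ny; ++y) out[lin(x, y, z, nx, ny)] = d[y];
    }
  // z pass
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      for (int z = 0; z < nz; ++z) f[z] = out[lin(x, y, z, nx, ny)];
      dt1d(f, d, v, zb, nz, spacing[2]);
      for (int z = 0; z < nz; ++z) out[lin(x, y, z, nx, ny)] = d[z];
    }
  return out;
}

// Signed distance: negative inside the mask, positive outside (mm).
// [[Rcpp::export]]
NumericVector cpp_signed_distance(LogicalVector mask, IntegerVector dim,
                                  NumericVector spacing) {
  const R_xlen_t n = mask.size();
  LogicalVector inv(n);
  for (R_xlen_t i = 0; i < n; ++i) inv[i] = !mask[i];
  NumericVector dout = cpp_edt_sq(mask, dim, spacing); // dist to fg (for bg voxels)
  NumericVector din = cpp_edt_sq(inv, dim, spacing);   // dist to bg (for fg voxels)
  NumericVector phi(n);
  for (R_xlen_t i = 0; i < n; ++i)
    phi[i] = mask[i] ? -std::sqrt(din[i]) : std::sqrt(dout[i]);
  return phi;
}

// Erode by a physical radius: keep foreground voxels whose centre is more
// than `radius` mm from the nearest background voxel centre.
// [[Rcpp::export]]
LogicalVector cpp_erode_physical(LogicalVector mask, IntegerVector dim,
                                 NumericVector spacing, double radius) {
  const R_xlen_t n = mask.size();
  LogicalVector inv(n);
  bool any_bg = false;
  for (R_xlen_t i = 0; i < n; ++i) { inv[i] = !mask[i]; any_bg = any_bg || inv[i]; }
  LogicalVector out(n);
  if (!any_bg) { // solid grid: nothing to erode against
    for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i];
    return out;
  }
  NumericVector d2 = cpp_edt_sq(inv, dim, spacing);
  const double r2 = radius * radius;
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] && d2[i] > r2;
  return out;
}

static void gauss_kernel(double sigma_vox, std::vector<double> &k) {
  int r = (int)std::ceil(4.0 * sigma_vox);
  if (r < 1) r = 1;
  k.assign(2 * r + 1, 0.0);
  double s = 0;
  for (int i = -r; i <= r; ++i) {
    const double w = std::exp(-0.5 * (i * i) / (sigma_vox * sigma_vox));
    k[i + r] = w; s += w;
  }
  for (double &w : k) w /= s;
}

// Separable Gaussian smoothing with physical width sigma (mm); border
// handling by edge replication. sigma = 0 returns a copy.
// [[Rcpp::export]]
NumericVector cpp_gaussian_smooth(NumericVector img, IntegerVector dim,
                                  NumericVector spacing, double sigma) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector cur = clone(img);
  if (sigma <= 0) return cur;
  NumericVector tmp(n);
  const int nd[3] = {nx, ny, nz};
  const int stride[3] = {1, nx, nx * ny};
  for (int axis = 0; axis < 3; ++axis) {
    const double sv = sigma / spacing[axis];
    if (sv < 1e-8) continue;
    std::vector<double> k;
    gauss_kernel(sv, k);
    const int r = ((int)k.size() - 1) / 2;
    const int na = nd[axis], st = stride[axis];
    // iterate over all lines along `axis`
    const int n1 = nd[(axis + 1) % 3], n2 = nd[(axis + 2) % 3];
    const int st1 = stride[(axis + 1) % 3], st2 = stride[(axis + 2) % 3];
    for (int j2 = 0; j2 < n2; ++j2)
      for (int j1 = 0; j1 < n1; ++j1) {
        const R_xlen_t base = (R_xlen_t)j1 * st1 + (R_xlen_t)j2 * st2;
        for (int i = 0; i < na; ++i) {
          double acc = 0;
          for (int t = -r; t <= r; ++t) {
            int ii = i + t;
            if (ii < 0) ii = 0; else if (ii >= na) ii = na - 1;
            acc += k[t + r] * cur[base + (R_xlen_t)ii * st];
          }
          tmp[base + (R_xlen_t)i * st] = acc;
        }
      }
    std::swap(cur, tmp);
  }
  return cur;
}

// Laplacian by central second differences with physical spacing; borders use
// replicated neighbours (zero second derivative across the face).
// [[Rcpp::export]]
NumericVector cpp_laplacian(NumericVector img, IntegerVector dim,
                            NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out((R_xlen_t)nx * ny * nz);
  const double ihx2 = 1.0 / (spacing[0] * spacing[0]);
  const double ihy2 = 1.0 / (spacing[1] * spacing[1]);
  const double ihz2 = 1.0 / (spacing[2] * spacing[2]);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const int i = lin(x, y, z, nx, ny);
        const double c = img[i];
        const double xm = img[lin(x > 0 ? x - 1 : x, y, z, nx, ny)];
        const double xp = img[lin(x < nx - 1 ? x + 1 : x, y, z, nx, ny)];
        const double ym = img[lin(x, y > 0 ? y - 1 : y, z, nx, ny)];
        const double yp = img[lin(x, y < ny - 1 ? y + 1 : y, z, nx, ny)];
        const double zm = img[lin(x, y, z > 0 ? z - 1 : z, nx, ny)];
        const double zp = img[lin(x, y, z < nz - 1 ? z + 1 : z, nx, ny)];
        out[i] = (xp - 2 * c + xm) * ihx2 + (yp - 2 * c + ym) * ihy2 +
                 (zp - 2 * c + zm) * ihz2;
      }
  return out;
}

// Level-set evolution with Godunov-upwind propagation driven by a speed
// field (here: the normalized Laplacian of the smoothed image) plus a mean-
// curvature regularizer. phi is negative inside; outward normal speed
// v = -prop * speed locks the zero level onto Laplacian zero crossings.
// [[Rcpp::export]]
NumericVector cpp_levelset_evolve(NumericVector phi0, NumericVector speed,
                                  IntegerVector dim, NumericVector spacing,
                                  int iterations, double prop_weight,
                                  double curv_weight) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector phi = clone(phi0);
  if (iterations <= 0) return phi;
  const double hx = spacing[0], hy = spacing[1], hz = spacing[2];
  const double hmin = std::min(hx, std::min(hy, hz));
  const double hmax = std::max(hx, std::max(hy, hz));
  double smax = 0;
  for (R_xlen_t i = 0; i < n; ++i) smax = std::max(smax, std::fabs(speed[i]));
  const double vmax = prop_weight * smax;
  double dt = 0.4 * hmin / std::max(vmax, 1e-12);
  if (curv_weight > 0) {
    const double sumh2 = 1.0 / (hx * hx) + 1.0 / (hy * hy) + 1.0 / (hz * hz);
    dt = std::min(dt, 0.45 / (curv_weight * sumh2));
  }
  // narrow band: the front can travel at most iterations*dt*vmax, so only
  // voxels within that distance (plus a safety margin) of the initial zero
  // level can change sign; everything else keeps its initial value.
  const double band = iterations * dt * std::max(vmax, curv_weight) + 3 * hmax;
  std::vector<int> active;
  active.reserve(n / 8);
  for (int z = 1; z < nz - 1; ++z)
    for (int y = 1; y < ny - 1; ++y)
      for (int x = 1; x < nx - 1; ++x) {
        const int i = lin(x, y, z, nx, ny);
        if (std::fabs(phi[i]) <= band) active.push_back(i);
      }
  const int sx = 1, sy = nx, sz2 = nx * ny;
  std::vector<double> upd(active.size());
  double *p = REAL(phi);
  const double *sp = REAL(speed);
  for (int it = 0; it < iterations; ++it) {
    for (size_t k = 0; k < active.size(); ++k) {
      const int i = active[k];
      const double c = p[i];
      const double xm = p[i - sx], xp = p[i + sx];
      const double ym = p[i - sy], yp = p[i + sy];
      const double zm = p[i - sz2], zp = p[i + sz2];
      const double Dmx = (c - xm) / hx, Dpx = (xp - c) / hx;
      const double Dmy = (c - ym) / hy, Dpy = (yp - c) / hy;
      const double Dmz = (c - zm) / hz, Dpz = (zp - c) / hz;
      const double v = -prop_weight * sp[i]; // outward normal speed
      double grad;
      if (v > 0) {
        const double ax = std::max(std::max(Dmx, 0.0), -std::min(Dpx, 0.0));
        const double ay = std::max(std::max(Dmy, 0.0), -std::min(Dpy, 0.0));
        const double az = std::max(std::max(Dmz, 0.0), -std::min(Dpz, 0.0));
        grad = std::sqrt(ax * ax + ay * ay + az * az);
      } else {
        const double ax = std::max(std::max(Dpx, 0.0), -std::min(Dmx, 0.0));
        const double ay = std::max(std::max(Dpy, 0.0), -std::min(Dmy, 0.0));
        const double az = std::max(std::max(Dpz, 0.0), -std::min(Dmz, 0.0));
        grad = std::sqrt(ax * ax + ay * ay + az * az);
      }
      double dphi = -v * grad;
      if (curv_weight > 0) {
        // mean curvature * |grad phi| via central differences
        const double px = (xp - xm) / (2 * hx);
        const double py = (yp - ym) / (2 * hy);
        const double pz = (zp - zm) / (2 * hz);
        const double g2 = px * px + py * py + pz * pz;
        if (g2 > 1e-12) {
          const double pxx = (xp - 2 * c + xm) / (hx * hx);
          const double pyy = (yp - 2 * c + ym) / (hy * hy);
          const double pzz = (zp - 2 * c + zm) / (hz * hz);
          const double pxy = (p[i + sx + sy] - p[i + sx - sy] -
                              p[i - sx + sy] + p[i - sx - sy]) / (4 * hx * hy);
          const double pxz = (p[i + sx + sz2] - p[i + sx - sz2] -
                              p[i - sx + sz2] + p[i - sx - sz2]) / (4 * hx * hz);
          const double pyz = (p[i + sy + sz2] - p[i + sy - sz2] -
                              p[i - sy + sz2] + p[i - sy - sz2]) / (4 * hy * hz);
          const double kg = (pxx * (py * py + pz * pz) + pyy * (px * px + pz * pz) +
                             pzz * (px * px + py * py) -
                             2 * (pxy * px * py + pxz * px * pz + pyz * py * pz)) / g2;
          dphi += curv_weight * kg;
        }
      }
      upd[k] = c + dt * dphi;
    }
    for (size_t k = 0; k < active.size(); ++k) p[active[k]] = upd[k];
  }
  return phi;
}
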