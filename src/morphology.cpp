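// 3-D image-analysis primitives used by the morphometry and scaffold
// modules: connected-component labeling (6/26 connectivity), exact Euclidean
// distance transform (Felzenszwalb-Huttenlocher, separable), separable
// Gaussian smoothing, trilinear resampling, h-maxima markers by grayscale
// reconstruction, marker-based watershed (priority flood), and 3-D local
// maxima detection.

#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <cstdint>
#include <limits>
using namespace Rcpp;

static inline R_xlen_t vidx(int x, int y, int z, int nx, int ny) {
  return (R_xlen_t)x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
}

static void neighbor_offsets(int conn, std::vector<std::array<int,3>>& off) {
  off.clear();
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        const int man = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (conn == 6 && man != 1) continue;
        off.push_back({dx, dy, dz});
      }
}

// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<std::array<int,3>> off;
  neighbor_offsets(connectivity, off);
  IntegerVector out(n, 0);
  int lbl = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || out[s] != 0) continue;
    ++lbl;
    stack.push_back(s);
    out[s] = lbl;
    while (!stack.empty()) {
      const R_xlen_t c = stack.back(); stack.pop_back();
      const int x = c % nx, y = (c / nx) % ny, z = c / ((R_xlen_t)nx * ny);
      for (auto& o : off) {
        const int xx = x + o[0], yy = y + o[1], zz = z + o[2];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
        const R_xlen_t cc = vidx(xx, yy, zz, nx, ny);
        if (mask[cc] && out[cc] == 0) { out[cc] = lbl; stack.push_back(cc); }
      }
    }
  }
  out.attr("dim") = dims;
  out.attr("n_labels") = lbl;
  return out;
}

// 1-D lower envelope of parabolas (squared distance transform)
static void edt1d(const std::vector<double>& f, std::vector<double>& d, int n,
                  std::vector<int>& v, std::vector<double>& zz) {
  int k = 0;
  v[0] = 0;
  zz[0] = -std::numeric_limits<double>::infinity();
  zz[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2.0 * q - 2.0 * v[k]);
      if (s <= zz[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    zz[k] = s;
    zz[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zz[k + 1] < q) ++k;
    d[q] = (q - v[k]) * (double)(q - v[k]) + f[v[k]];
  }
}

// Squared Euclidean distance (in voxels) from each true voxel of `mask` to
// the nearest false voxel.
// [[Rcpp::export]]
NumericVector edt_squared_cpp(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double INF = 1e18;
  std::vector<double> d(n);
  for (R_xlen_t i = 0; i < n; ++i) d[i] = mask[i] ? INF : 0.0;
  const int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), g(nmax), zz(nmax + 1);
  std::vector<int> v(nmax);
  // pass along x
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) f[x] = d[vidx(x, y, z, nx, ny)];
      edt1d(f, g, nx, v, zz);
      for (int x = 0; x < nx; ++x) d[vidx(x, y, z, nx, ny)] = g[x];
    }
  // pass along y
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) f[y] = d[vidx(x, y, z, nx, ny)];
      edt1d(f, g, ny, v, zz);
      for (int y = 0; y < ny; ++y) d[vidx(x, y, z, nx, ny)] = g[y];
    }
  // pass along z
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      for (int z = 0; z < nz; ++z) f[z] = d[vidx(x, y, z, nx, ny)];
      edt1d(f, g, nz, v, zz);
      for (int z = 0; z < nz; ++z) d[vidx(x, y, z, nx, ny)] = g[z];
    }
  NumericVector out(n);
  std::copy(d.begin(), d.end(), out.begin());
  out.attr("dim") = dims;
  return out;
}

// Separable Gaussian blur with reflective padding; sigma in voxels per axis.
// [[Rcpp::export]]
NumericVector gaussian_blur_cpp(NumericVector vol, IntegerVector dims,
                                NumericVector sigma) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> a(vol.begin(), vol.end()), b(n);
  const int nsz[3] = {nx, ny, nz};
  for (int axis = 0; axis < 3; ++axis) {
    const double s = sigma[axis];
    if (s <= 0) continue;
    const int r = std::max(1, (int)std::ceil(3.0 * s));
    std::vector<double> k(2 * r + 1);
    double ksum = 0.0;
    for (int i = -r; i <= r; ++i) { k[i + r] = std::exp(-0.5 * i * i / (s * s)); ksum += k[i + r]; }
    for (auto& kv : k) kv /= ksum;
    const int len = nsz[axis];
    for (R_xlen_t c = 0; c < n; ++c) {
      const int x = c % nx, y = (c / nx) % ny, z = c / ((R_xlen_t)nx * ny);
      int pos[3] = {x, y, z};
      double acc = 0.0;
      for (int i = -r; i <= r; ++i) {
        int p = pos[axis] + i;
        while (p < 0 || p >= len) {            // reflect (kernel may exceed axis)
          if (p < 0) p = -p - 1;
          if (p >= len) p = 2 * len - p - 1;
        }
        int q[3] = {x, y, z};
        q[axis] = p;
        acc += k[i + r] * a[vidx(q[0], q[1], q[2], nx, ny)];
      }
      b[c] = acc;
    }
    std::swap(a, b);
  }
  NumericVector out(n);
  std::copy(a.begin(), a.end(), out.begin());
  out.attr("dim") = dims;
  return out;
}

// Trilinear resampling onto a new grid. Output voxel centers are placed at
// physical positions (i + 0.5) * new_sp along each axis, sampled from input
// voxel centers at (j + 0.5) * old_sp, with edge clamping.
// [[Rcpp::export]]
NumericVector resample_trilinear_cpp(NumericVector vol, IntegerVector dims,
                                     NumericVector old_sp, IntegerVector new_dims,
                                     NumericVector new_sp) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int mx = new_dims[0], my = new_dims[1], mz = new_dims[2];
  NumericVector out((R_xlen_t)mx * my * mz);
  for (int z = 0; z < mz; ++z)
    for (int y = 0; y < my; ++y)
      for (int x = 0; x < mx; ++x) {
        const double px = ((x + 0.5) * new_sp[0]) / old_sp[0] - 0.5;
        const double py = ((y + 0.5) * new_sp[1]) / old_sp[1] - 0.5;
        const double pz = ((z + 0.5) * new_sp[2]) / old_sp[2] - 0.5;
        int x0 = (int)std::floor(px), y0 = (int)std::floor(py), z0 = (int)std::floor(pz);
        double fx = px - x0, fy = py - y0, fz = pz - z0;
        auto cl = [](int v, int hi) { return v < 0 ? 0 : (v > hi ? hi : v); };
        const int x1 = cl(x0 + 1, nx - 1), y1 = cl(y0 + 1, ny - 1), z1 = cl(z0 + 1, nz - 1);
        x0 = cl(x0, nx - 1); y0 = cl(y0, ny - 1); z0 = cl(z0, nz - 1);
        double acc = 0.0;
        for (int dz = 0; dz < 2; ++dz)
          for (int dy = 0; dy < 2; ++dy)
            for (int dx = 0; dx < 2; ++dx) {
              const double w = (dx ? fx : 1 - fx) * (dy ? fy : 1 - fy) * (dz ? fz : 1 - fz);
              acc += w * vol[vidx(dx ? x1 : x0, dy ? y1 : y0, dz ? z1 : z0, nx, ny)];
            }
        out[vidx(x, y, z, mx, my)] = acc;
      }
  out.attr("dim") = new_dims;
  return out;
}

// Grayscale reconstruction of `marker` under `maskimg` (marker <= maskimg),
// hybrid raster/queue algorithm, 26-connectivity.
static std::vector<double> reconstruct(const std::vector<double>& marker,
                                       const double* maskimg,
                                       int nx, int ny, int nz) {
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> J(marker);
  std::vector<std::array<int,3>> off;
  neighbor_offsets(26, off);
  // iterate raster forward/backward sweeps until stable (bounded passes),
  // volumes here are small enough that this converges quickly
  bool changed = true;
  int guard = 0;
  while (changed && guard++ < 256) {
    changed = false;
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          const R_xlen_t c = vidx(x, y, z, nx, ny);
          double m = J[c];
          for (auto& o : off) {
            const int xx = x + o[0], yy = y + o[1], zz = z + o[2];
            if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
            const double v = J[vidx(xx, yy, zz, nx, ny)];
            if (v > m) m = v;
          }
          m = std::min(m, maskimg[c]);
          if (m > J[c]) { J[c] = m; changed = true; }
        }
    for (int z = nz - 1; z >= 0; --z)
      for (int y = ny - 1; y >= 0; --y)
        for (int x = nx - 1; x >= 0; --x) {
          const R_xlen_t c = vidx(x, y, z, nx, ny);
          double m = J[c];
          for (auto& o : off) {
            const int xx = x + o[0], yy = y + o[1], zz = z + o[2];
            if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
            const double v = J[vidx(xx, yy, zz, nx, ny)];
            if (v > m) m = v;
          }
          m = std::min(m, maskimg[c]);
          if (m > J[c]) { J[c] = m; changed = true; }
        }
  }
  return J;
}

// Markers for watershed: connected plateaus of the h-maxima transform of
// `dist` (restricted to `mask`) that have no higher neighbor. Ties between
// touching plateaus are impossible by construction; labels are assigned in
// raster order (lowest voxel index first).
// [[Rcpp::export]]
IntegerVector hmaxima_markers_cpp(NumericVector dist, LogicalVector mask,
                                  IntegerVector dims, double h) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> d(n), marker(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    d[i] = mask[i] ? dist[i] : -1.0;
    marker[i] = d[i] - h;
  }
  std::vector<double> rec = reconstruct(marker, d.data(), nx, ny, nz);
  // regional maxima of the reconstruction: plateau components with no
  // strictly greater neighbor
  std::vector<std::array<int,3>> off;
  neighbor_offsets(26, off);
  IntegerVector out(n, 0);
  std::vector<int8_t> state(n, 0); // 0 unvisited, 1 in-plateau, 2 rejected
  int lbl = 0;
  std::vector<R_xlen_t> comp, stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || state[s] != 0) continue;
    const double v = rec[s];
    comp.clear(); stack.clear();
    stack.push_back(s);
    state[s] = 1;
    bool is_max = true;
    while (!stack.empty()) {
      const R_xlen_t c = stack.back(); stack.pop_back();
      comp.push_back(c);
      const int x = c % nx, y = (c / nx) % ny, z = c / ((R_xlen_t)nx * ny);
      for (auto& o : off) {
        const int xx = x + o[0], yy = y + o[1], zz = z + o[2];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
        const R_xlen_t cc = vidx(xx, yy, zz, nx, ny);
        if (rec[cc] > v) is_max = false;
        else if (rec[cc] == v && mask[cc] && state[cc] == 0) {
          state[cc] = 1;
          stack.push_back(cc);
        }
      }
    }
    if (is_max) {
      ++lbl;
      for (auto c : comp) out[c] = lbl;
    } else {
      for (auto c : comp) state[c] = 2;
    }
  }
  out.attr("dim") = dims;
  out.attr("n_labels") = lbl;
  return out;
}

// Marker-based watershed by priority flood on -priority (largest priority
// flooded first), restricted to mask, 26-connectivity. Ties resolved by
// insertion order (lowest marker label reaches first).
// [[Rcpp::export]]
IntegerVector watershed_cpp(NumericVector priority, IntegerVector markers,
                            LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<std::array<int,3>> off;
  neighbor_offsets(26, off);
  IntegerVector out(n, 0);
  typedef std::tuple<double, uint64_t, R_xlen_t> Item; // (-prio, order, idx)
  std::priority_queue<Item, std::vector<Item>, std::greater<Item>> pq;
  uint64_t order = 0;
  for (R_xlen_t i = 0; i < n; ++i)
    if (markers[i] > 0 && mask[i]) {
      out[i] = markers[i];
      pq.emplace(-priority[i], order++, i);
    }
  while (!pq.empty()) {
    const R_xlen_t c = std::get<2>(pq.top());
    pq.pop();
    const int lbl = out[c];
    const int x = c % nx, y = (c / nx) % ny, z = c / ((R_xlen_t)nx * ny);
    for (auto& o : off) {
      const int xx = x + o[0], yy = y + o[1], zz = z + o[2];
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
      const R_xlen_t cc = vidx(xx, yy, zz, nx, ny);
      if (!mask[cc] || out[cc] != 0) continue;
      out[cc] = lbl;
      pq.emplace(-priority[cc], order++, cc);
    }
  }
  out.attr("dim") = dims;
  return out;
}

// 3-D local maxima above `floor`: voxel strictly greater than all 26
// neighbors, with plateau ties broken toward the lowest linear index.
// Returns 0-based linear indices.
// [[Rcpp::export]]
IntegerVector local_maxima_cpp(NumericVector vol, IntegerVector dims,
                               double floor_val) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<std::array<int,3>> off;
  neighbor_offsets(26, off);
  std::vector<int> keep;
  for (R_xlen_t c = 0; c < n; ++c) {
    const double v = vol[c];
    if (!(v > floor_val)) continue;
    const int x = c % nx, y = (c / nx) % ny, z = c / ((R_xlen_t)nx * ny);
    bool ok = true, has_smaller = false;
    for (auto& o : off) {
      const int xx = x + o[0], yy = y + o[1], zz = z + o[2];
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
      const R_xlen_t cc = vidx(xx, yy, zz, nx, ny);
      if (vol[cc] > v || (vol[cc] == v && cc < c)) { ok = false; break; }
      if (vol[cc] < v) has_smaller = true;
    }
    // a flat plateau spanning its whole neighbourhood is not a maximum
    if (ok && has_smaller) keep.push_back((int)c);
  }
  return IntegerVector(keep.begin(), keep.end());
}

// Per-label voxel counts and centroids (voxel coordinates, 0-based centers).
// [[Rcpp::export]]
List label_stats_cpp(IntegerVector labels, IntegerVector dims, int nlab) {
  const int nx = dims[0], ny = dims[1];
  const R_xlen_t n = labels.size();
  NumericVector count(nlab), cx(nlab), cy(nlab), cz(nlab);
  for (R_xlen_t c = 0; c < n; ++c) {
    const int l = labels[c];
    if (l <= 0) continue;
    const int x = c % nx, y = (c / nx) % ny, z = c / ((R_xlen_t)nx * ny);
    count[l - 1] += 1;
    cx[l - 1] += x; cy[l - 1] += y; cz[l - 1] += z;
  }
  for (int l = 0; l < nlab; ++l)
    if (count[l] > 0) { cx[l] /= count[l]; cy[l] /= count[l]; cz[l] /= count[l]; }
  return List::create(_["count"] = count, _["cx"] = cx, _["cy"] = cy, _["cz"] = cz);
}
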