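// Low-level kernels shared by the image-enhancement, sparse-mask,
// cell-segmentation and skeletonization stages.
//
// Volume convention: dims are (nz, ny, nx); linear index (0-based) is
//   idx = z + nz * (y + ny * x)
// which matches an R array with dim = c(nz, ny, nx).

#include <Rcpp.h>
#include <vector>
#include <array>
#include <algorithm>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

static inline void idx2zyx(long long idx, int nz, int ny,
                           int& z, int& y, int& x) {
  z = (int)(idx % nz);
  long long r = idx / nz;
  y = (int)(r % ny);
  x = (int)(r / ny);
}

static inline long long zyx2idx(int z, int y, int x, int nz, int ny) {
  return (long long)z + (long long)nz * ((long long)y + (long long)ny * x);
}

// mirror (symmetric, half-sample) boundary reflection
static inline int reflect_index(int i, int L) {
  if (L == 1) return 0;
  while (i < 0 || i >= L) {
    if (i < 0) i = -i - 1;
    if (i >= L) i = 2 * L - i - 1;
  }
  return i;
}

// ---------------------------------------------------------------------------
// Separable 3D convolution with mirror boundary.  Kernels must have odd
// length; a length-1 kernel simply scales the axis.
// ---------------------------------------------------------------------------

static void conv_axis(const std::vector<double>& src, std::vector<double>& dst,
                      int nz, int ny, int nx, int axis, const NumericVector& k) {
  const int K = k.size();
  const int half = K / 2;
  const long long sz = 1, sy = nz, sx = (long long)nz * ny;
  int L;
  long long stride;
  int d1, d2;
  long long s1, s2;
  if (axis == 0) { L = nz; stride = sz; d1 = ny; s1 = sy; d2 = nx; s2 = sx; }
  else if (axis == 1) { L = ny; stride = sy; d1 = nz; s1 = sz; d2 = nx; s2 = sx; }
  else { L = nx; stride = sx; d1 = nz; s1 = sz; d2 = ny; s2 = sy; }
  // gather each line into a mirror-padded contiguous buffer: the inner
  // product then runs branch-free over sequential memory
  std::vector<double> line(L + 2 * half);
  const double* kk = &k[0];
  for (int b = 0; b < d2; b++) {
    for (int a = 0; a < d1; a++) {
      const long long base = (long long)a * s1 + (long long)b * s2;
      for (int i = 0; i < L; i++) line[half + i] = src[base + i * stride];
      for (int j = 0; j < half; j++) {
        line[j] = line[half + reflect_index(j - half, L)];
        line[half + L + j] = line[half + reflect_index(L + j, L)];
      }
      for (int i = 0; i < L; i++) {
        double acc = 0.0;
        const double* p = &line[i];
        for (int j = 0; j < K; j++) acc += kk[j] * p[j];
        dst[base + i * stride] = acc;
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv_sep3_cpp(NumericVector vol, IntegerVector dim,
                            NumericVector kz, NumericVector ky,
                            NumericVector kx) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const long long n = (long long)nz * ny * nx;
  std::vector<double> a(vol.begin(), vol.end());
  std::vector<double> b(n);
  conv_axis(a, b, nz, ny, nx, 0, kz);
  conv_axis(b, a, nz, ny, nx, 1, ky);
  conv_axis(a, b, nz, ny, nx, 2, kx);
  NumericVector out(n);
  std::copy(b.begin(), b.end(), out.begin());
  return out;
}

// Direct (non-separable) 3D convolution; for small kernels / small volumes.
// [[Rcpp::export]]
NumericVector conv3_direct_cpp(NumericVector vol, IntegerVector dim,
                               NumericVector ker, IntegerVector kdim) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const int mz = kdim[0], my = kdim[1], mx = kdim[2];
  const int hz = mz / 2, hy = my / 2, hx = mx / 2;
  NumericVector out((long long)nz * ny * nx);
  for (int x = 0; x < nx; x++)
    for (int y = 0; y < ny; y++)
      for (int z = 0; z < nz; z++) {
        double acc = 0.0;
        for (int kx = 0; kx < mx; kx++) {
          int xx = reflect_index(x + kx - hx, nx);
          for (int ky = 0; ky < my; ky++) {
            int yy = reflect_index(y + ky - hy, ny);
            for (int kz = 0; kz < mz; kz++) {
              int zz = reflect_index(z + kz - hz, nz);
              acc += ker[kz + mz * (ky + my * kx)] *
                     vol[zyx2idx(zz, yy, xx, nz, ny)];
            }
          }
        }
        out[zyx2idx(z, y, x, nz, ny)] = acc;
      }
  return out;
}

// ---------------------------------------------------------------------------
// Sparse-mask morphology.  idx1 is a sorted 1-based vector of linear indices;
// off is a k x 3 matrix of (dz, dy, dx) structuring-element offsets.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector mask_dilate_cpp(IntegerVector idx1, IntegerVector dim,
                              IntegerMatrix off) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const long long n = (long long)nz * ny * nx;
  std::vector<uint8_t> res(n, 0);
  const int k = off.nrow();
  for (R_xlen_t i = 0; i < idx1.size(); i++) {
    int z, y, x;
    idx2zyx((long long)idx1[i] - 1, nz, ny, z, y, x);
    for (int j = 0; j < k; j++) {
      int zz = z + off(j, 0), yy = y + off(j, 1), xx = x + off(j, 2);
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
        continue;
      res[zyx2idx(zz, yy, xx, nz, ny)] = 1;
    }
  }
  long long cnt = 0;
  for (long long i = 0; i < n; i++) cnt += res[i];
  IntegerVector out(cnt);
  long long p = 0;
  for (long long i = 0; i < n; i++)
    if (res[i]) out[p++] = (int)(i + 1);
  return out;
}

// Erosion: a voxel survives iff every offset lands in-domain on an active
// voxel (out-of-domain counts as background).
// [[Rcpp::export]]
IntegerVector mask_erode_cpp(IntegerVector idx1, IntegerVector dim,
                             IntegerMatrix off) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const long long n = (long long)nz * ny * nx;
  std::vector<uint8_t> act(n, 0);
  for (R_xlen_t i = 0; i < idx1.size(); i++) act[idx1[i] - 1] = 1;
  const int k = off.nrow();
  std::vector<int> keep;
  keep.reserve(idx1.size());
  for (R_xlen_t i = 0; i < idx1.size(); i++) {
    int z, y, x;
    idx2zyx((long long)idx1[i] - 1, nz, ny, z, y, x);
    bool ok = true;
    for (int j = 0; j < k && ok; j++) {
      int zz = z + off(j, 0), yy = y + off(j, 1), xx = x + off(j, 2);
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx ||
          !act[zyx2idx(zz, yy, xx, nz, ny)])
        ok = false;
    }
    if (ok) keep.push_back(idx1[i]);
  }
  return IntegerVector(keep.begin(), keep.end());
}

// Surface voxels: active with at least one inactive (or out-of-domain) face
// neighbor (6-connectivity).
// [[Rcpp::export]]
IntegerVector mask_surface_cpp(IntegerVector idx1, IntegerVector dim) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const long long n = (long long)nz * ny * nx;
  std::vector<uint8_t> act(n, 0);
  for (R_xlen_t i = 0; i < idx1.size(); i++) act[idx1[i] - 1] = 1;
  static const int F[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};
  std::vector<int> keep;
  for (R_xlen_t i = 0; i < idx1.size(); i++) {
    int z, y, x;
    idx2zyx((long long)idx1[i] - 1, nz, ny, z, y, x);
    bool surf = false;
    for (int j = 0; j < 6 && !surf; j++) {
      int zz = z + F[j][0], yy = y + F[j][1], xx = x + F[j][2];
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx ||
          !act[zyx2idx(zz, yy, xx, nz, ny)])
        surf = true;
    }
    if (surf) keep.push_back(idx1[i]);
  }
  return IntegerVector(keep.begin(), keep.end());
}

static void neighbor_offsets(int connectivity, std::vector<std::array<int,3>>& off) {
  off.clear();
  for (int dx = -1; dx <= 1; dx++)
    for (int dy = -1; dy <= 1; dy++)
      for (int dz = -1; dz <= 1; dz++) {
        if (dz == 0 && dy == 0 && dx == 0) continue;
        int m = std::abs(dz) + std::abs(dy) + std::abs(dx);
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        off.push_back({dz, dy, dx});
      }
}

// Connected components over a sparse mask.  Labels are assigned in order of
// each component's smallest linear index, so labeling is deterministic.
// [[Rcpp::export]]
IntegerVector label_components_cpp(IntegerVector idx1, IntegerVector dim,
                                   int connectivity) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const long long n = (long long)nz * ny * nx;
  std::vector<int> vid(n, -1);
  for (R_xlen_t i = 0; i < idx1.size(); i++) vid[idx1[i] - 1] = (int)i;
  std::vector<std::array<int,3>> off;
  neighbor_offsets(connectivity, off);
  IntegerVector labels(idx1.size(), 0);
  int next = 0;
  std::vector<long long> queue;
  for (R_xlen_t i = 0; i < idx1.size(); i++) {
    if (labels[i]) continue;
    next++;
    labels[i] = next;
    queue.clear();
    queue.push_back((long long)idx1[i] - 1);
    while (!queue.empty()) {
      long long cur = queue.back();
      queue.pop_back();
      int z, y, x;
      idx2zyx(cur, nz, ny, z, y, x);
      for (size_t j = 0; j < off.size(); j++) {
        int zz = z + off[j][0], yy = y + off[j][1], xx = x + off[j][2];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
          continue;
        long long nb = zyx2idx(zz, yy, xx, nz, ny);
        int v = vid[nb];
        if (v >= 0 && !labels[v]) {
          labels[v] = next;
          queue.push_back(nb);
        }
      }
    }
  }
  return labels;
}

// ---------------------------------------------------------------------------
// Seeded eikonal fast sweeping restricted to a sparse mask.
//
// Local update: the first-order upwind eikonal solve over the three axes,
// tightened with a 26-neighbor graph relaxation so that geodesics along
// single-voxel-wide diagonal paths are still finite and never exceed the
// 26-neighbor Dijkstra distance.  Gauss-Seidel sweeps run in the 8 axis
// orderings until the largest update falls below `tol`.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector fastsweep_cpp(IntegerVector idx1, IntegerVector seed1,
                            IntegerVector dim, NumericVector spacing,
                            double tol, int max_rounds) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const long long n = (long long)nz * ny * nx;
  const double hz = spacing[0], hy = spacing[1], hx = spacing[2];
  const double INF = R_PosInf;
  std::vector<uint8_t> act(n, 0);
  for (R_xlen_t i = 0; i < idx1.size(); i++) act[idx1[i] - 1] = 1;
  std::vector<double> dist(n, INF);
  for (R_xlen_t i = 0; i < seed1.size(); i++) {
    long long s = (long long)seed1[i] - 1;
    if (act[s]) dist[s] = 0.0;
  }
  // mask bounding box
  int z0 = nz, z1 = -1, y0 = ny, y1 = -1, x0 = nx, x1 = -1;
  for (R_xlen_t i = 0; i < idx1.size(); i++) {
    int z, y, x;
    idx2zyx((long long)idx1[i] - 1, nz, ny, z, y, x);
    z0 = std::min(z0, z); z1 = std::max(z1, z);
    y0 = std::min(y0, y); y1 = std::max(y1, y);
    x0 = std::min(x0, x); x1 = std::max(x1, x);
  }
  if (z1 < 0) return NumericVector(0);
  // 26-neighborhood with physical step lengths
  std::vector<std::array<int,3>> noff;
  neighbor_offsets(26, noff);
  std::vector<double> nd(noff.size());
  for (size_t j = 0; j < noff.size(); j++) {
    double dz = noff[j][0] * hz, dy = noff[j][1] * hy, dx = noff[j][2] * hx;
    nd[j] = std::sqrt(dz * dz + dy * dy + dx * dx);
  }
  const double h[3] = {hz, hy, hx};

  auto local_update = [&](int z, int y, int x, long long cur) -> double {
    // axis-wise upwind values
    double a[3];
    a[0] = INF;
    if (z > 0 && act[cur - 1]) a[0] = dist[cur - 1];
    if (z < nz - 1 && act[cur + 1]) a[0] = std::min(a[0], dist[cur + 1]);
    a[1] = INF;
    if (y > 0 && act[cur - nz]) a[1] = dist[cur - nz];
    if (y < ny - 1 && act[cur + nz]) a[1] = std::min(a[1], dist[cur + nz]);
    a[2] = INF;
    long long sxy = (long long)nz * ny;
    if (x > 0 && act[cur - sxy]) a[2] = dist[cur - sxy];
    if (x < nx - 1 && act[cur + sxy]) a[2] = std::min(a[2], dist[cur + sxy]);
    // sort (a, h) pairs by a
    int ord[3] = {0, 1, 2};
    if (a[ord[0]] > a[ord[1]]) std::swap(ord[0], ord[1]);
    if (a[ord[1]] > a[ord[2]]) std::swap(ord[1], ord[2]);
    if (a[ord[0]] > a[ord[1]]) std::swap(ord[0], ord[1]);
    double u = INF;
    if (R_FINITE(a[ord[0]])) {
      u = a[ord[0]] + h[ord[0]];
      if (R_FINITE(a[ord[1]]) && u > a[ord[1]]) {
        // solve sum over first k axes of ((u - a_i)/h_i)^2 = 1
        for (int k = 2; k <= 3; k++) {
          if (k == 3 && (!R_FINITE(a[ord[2]]) || u <= a[ord[2]])) break;
          double A = 0, B = 0, C = -1;
          for (int m = 0; m < k; m++) {
            double c = 1.0 / (h[ord[m]] * h[ord[m]]);
            A += c;
            B += c * a[ord[m]];
            C += c * a[ord[m]] * a[ord[m]];
          }
          double disc = B * B - A * C;
          if (disc < 0) break;
          double u2 = (B + std::sqrt(disc)) / A;
          if (u2 < u) u = u2;
        }
      }
    }
    // 26-neighbor graph relaxation
    for (size_t j = 0; j < noff.size(); j++) {
      int zz = z + noff[j][0], yy = y + noff[j][1], xx = x + noff[j][2];
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
        continue;
      long long nb = zyx2idx(zz, yy, xx, nz, ny);
      if (act[nb] && R_FINITE(dist[nb]) && dist[nb] + nd[j] < u)
        u = dist[nb] + nd[j];
    }
    return u;
  };

  for (int round = 0; round < max_rounds; round++) {
    double maxchg = 0.0;
    for (int sweep = 0; sweep < 8; sweep++) {
      const int zs = (sweep & 1) ? -1 : 1;
      const int ys = (sweep & 2) ? -1 : 1;
      const int xs = (sweep & 4) ? -1 : 1;
      const int zb = zs > 0 ? z0 : z1, ze = zs > 0 ? z1 + 1 : z0 - 1;
      const int yb = ys > 0 ? y0 : y1, ye = ys > 0 ? y1 + 1 : y0 - 1;
      const int xb = xs > 0 ? x0 : x1, xe = xs > 0 ? x1 + 1 : x0 - 1;
      for (int x = xb; x != xe; x += xs)
        for (int y = yb; y != ye; y += ys)
          for (int z = zb; z != ze; z += zs) {
            long long cur = zyx2idx(z, y, x, nz, ny);
            if (!act[cur] || dist[cur] == 0.0) continue;
            double u = local_update(z, y, x, cur);
            if (u < dist[cur]) {
              double chg = R_FINITE(dist[cur]) ? dist[cur] - u : INF;
              if (chg > maxchg) maxchg = chg;
              dist[cur] = u;
            }
          }
    }
    if (maxchg < tol) break;
  }
  NumericVector out(idx1.size());
  for (R_xlen_t i = 0; i < idx1.size(); i++) out[i] = dist[idx1[i] - 1];
  return out;
}

// ---------------------------------------------------------------------------
// Surface graph: vertices are the given (sorted) voxels; edges join
// 26-adjacent pairs.  Returns an m x 2 matrix of 1-based vertex indices.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix surface_edges_cpp(IntegerVector idx1, IntegerVector dim) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const long long n = (long long)nz * ny * nx;
  std::vector<int> vid(n, -1);
  for (R_xlen_t i = 0; i < idx1.size(); i++) vid[idx1[i] - 1] = (int)i;
  // half of the 26-neighborhood (lexicographically positive offsets)
  std::vector<std::array<int,3>> half;
  for (int dx = -1; dx <= 1; dx++)
    for (int dy = -1; dy <= 1; dy++)
      for (int dz = -1; dz <= 1; dz++) {
        if (dz == 0 && dy == 0 && dx == 0) continue;
        if (dx > 0 || (dx == 0 && dy > 0) || (dx == 0 && dy == 0 && dz > 0))
          half.push_back({dz, dy, dx});
      }
  std::vector<int> eu, ev;
  for (R_xlen_t i = 0; i < idx1.size(); i++) {
    int z, y, x;
    idx2zyx((long long)idx1[i] - 1, nz, ny, z, y, x);
    for (size_t j = 0; j < half.size(); j++) {
      int zz = z + half[j][0], yy = y + half[j][1], xx = x + half[j][2];
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
        continue;
      int v = vid[zyx2idx(zz, yy, xx, nz, ny)];
      if (v >= 0) {
        eu.push_back((int)i + 1);
        ev.push_back(v + 1);
      }
    }
  }
  IntegerMatrix out(eu.size(), 2);
  for (size_t i = 0; i < eu.size(); i++) {
    out(i, 0) = eu[i];
    out(i, 1) = ev[i];
  }
  return out;
}

// ---------------------------------------------------------------------------
// One light-edge matching coarsening step: maximal matching preferring
// shortest edges (ties broken by the smaller, then larger, endpoint id);
// matched pairs contract to their weight-averaged midpoint.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List coarsen_step_cpp(NumericMatrix pos, NumericVector w, IntegerMatrix edges) {
  const int n = pos.nrow();
  const int m = edges.nrow();
  std::vector<double> len(m);
  std::vector<int> emin(m), emax(m);
  for (int e = 0; e < m; e++) {
    int u = edges(e, 0) - 1, v = edges(e, 1) - 1;
    emin[e] = std::min(u, v);
    emax[e] = std::max(u, v);
    double d = 0;
    for (int c = 0; c < 3; c++) {
      double t = pos(u, c) - pos(v, c);
      d += t * t;
    }
    len[e] = d;
  }
  std::vector<int> ord(m);
  for (int e = 0; e < m; e++) ord[e] = e;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (len[a] != len[b]) return len[a] < len[b];
    if (emin[a] != emin[b]) return emin[a] < emin[b];
    return emax[a] < emax[b];
  });
  std::vector<int> partner(n, -1);
  for (int t = 0; t < m; t++) {
    int e = ord[t];
    int u = emin[e], v = emax[e];
    if (u == v) continue;
    if (partner[u] < 0 && partner[v] < 0) {
      partner[u] = v;
      partner[v] = u;
    }
  }
  std::vector<int> map(n, -1);
  int nid = 0;
  for (int i = 0; i < n; i++) {
    if (partner[i] >= 0 && partner[i] < i) {
      map[i] = map[partner[i]];
    } else {
      map[i] = nid++;
    }
  }
  NumericMatrix npos(nid, 3);
  NumericVector nw(nid);
  for (int i = 0; i < n; i++) {
    if (partner[i] >= 0 && partner[i] < i) continue;  // handled by rep
    int id = map[i];
    if (partner[i] > i) {
      int j = partner[i];
      double tw = w[i] + w[j];
      for (int c = 0; c < 3; c++)
        npos(id, c) = (w[i] * pos(i, c) + w[j] * pos(j, c)) / tw;
      nw[id] = tw;
    } else {
      for (int c = 0; c < 3; c++) npos(id, c) = pos(i, c);
      nw[id] = w[i];
    }
  }
  // remap, dedupe and drop self-loop edges
  std::vector<long long> keys;
  keys.reserve(m);
  for (int e = 0; e < m; e++) {
    int u = map[emin[e]], v = map[emax[e]];
    if (u == v) continue;
    if (u > v) std::swap(u, v);
    keys.push_back((long long)u * nid + v);
  }
  std::sort(keys.begin(), keys.end());
  keys.erase(std::unique(keys.begin(), keys.end()), keys.end());
  IntegerMatrix nedges(keys.size(), 2);
  for (size_t e = 0; e < keys.size(); e++) {
    nedges(e, 0) = (int)(keys[e] / nid) + 1;
    nedges(e, 1) = (int)(keys[e] % nid) + 1;
  }
  IntegerVector rmap(n);
  for (int i = 0; i < n; i++) rmap[i] = map[i] + 1;
  return List::create(_["pos"] = npos, _["weight"] = nw,
                      _["edges"] = nedges, _["map"] = rmap);
}

// ---------------------------------------------------------------------------
// Graph components (CSR adjacency, 0-based), restricted to `keep` vertices.
// Component ids are assigned in ascending order of the smallest member.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector graph_components_cpp(IntegerVector xadj, IntegerVector adjncy,
                                   LogicalVector keep) {
  const int n = xadj.size() - 1;
  IntegerVector comp(n, 0);
  int next = 0;
  std::vector<int> stack;
  for (int i = 0; i < n; i++) {
    if (!keep[i] || comp[i]) continue;
    next++;
    comp[i] = next;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      int v = stack.back();
      stack.pop_back();
      for (int p = xadj[v]; p < xadj[v + 1]; p++) {
        int u = adjncy[p];
        if (keep[u] && !comp[u]) {
          comp[u] = next;
          stack.push_back(u);
        }
      }
    }
  }
  return comp;
}

// ---------------------------------------------------------------------------
// Local-separator search.
//
// A ball grows outward from a seed vertex in breadth-first rings.  Before
// each expansion the current front (unvisited neighbors of the ball) is
// tested for connectivity; when it splits into >= 2 induced components the
// ball is a separator candidate, which is then greedily minimized: vertices
// are dropped (outermost first) while the "local neighborhood splits"
// property holds, i.e. the subgraph induced on the neighbors of the set has
// >= 2 components.
// ---------------------------------------------------------------------------

namespace {

struct SepCtx {
  const int* xadj;
  const int* adjncy;
  int n;
  std::vector<int> vis, fmark, smark, nmark;
  int vepoch = 0, fepoch = 0, sepoch = 0, nepoch = 0;
  SepCtx(const int* xa, const int* ad, int n_)
      : xadj(xa), adjncy(ad), n(n_),
        vis(n_, 0), fmark(n_, 0), smark(n_, 0), nmark(n_, 0) {}

  // number of connected components of the subgraph induced on `verts`
  int induced_components(const std::vector<int>& verts) {
    fepoch++;
    for (int v : verts) fmark[v] = fepoch;
    int comps = 0;
    nepoch++;
    std::vector<int> stack;
    for (int v : verts) {
      if (nmark[v] == nepoch) continue;
      comps++;
      nmark[v] = nepoch;
      stack.push_back(v);
      while (!stack.empty()) {
        int c = stack.back();
        stack.pop_back();
        for (int p = xadj[c]; p < xadj[c + 1]; p++) {
          int u = adjncy[p];
          if (fmark[u] == fepoch && nmark[u] != nepoch) {
            nmark[u] = nepoch;
            stack.push_back(u);
          }
        }
      }
    }
    return comps;
  }

  // does the neighbor set of S (outside S) split into >= 2 components?
  bool separates(const std::vector<int>& S) {
    sepoch++;
    for (int v : S) smark[v] = sepoch;
    std::vector<int> nb;
    fepoch++;  // reuse fmark as "already collected"
    for (int v : S)
      for (int p = xadj[v]; p < xadj[v + 1]; p++) {
        int u = adjncy[p];
        if (smark[u] != sepoch && fmark[u] != fepoch) {
          fmark[u] = fepoch;
          nb.push_back(u);
        }
      }
    if (nb.empty()) return false;
    return induced_components(nb) >= 2;
  }

  // grow a ball from seed; returns true if the front split (ball in `ball`,
  // in BFS order).  `exhausted` reports that the component ran out without a
  // split (closed surface case).
  bool grow(int seed, int max_ball, std::vector<int>& ball, bool& exhausted) {
    exhausted = false;
    vepoch++;
    ball.clear();
    ball.push_back(seed);
    vis[seed] = vepoch;
    std::vector<int> front;
    for (int p = xadj[seed]; p < xadj[seed + 1]; p++) {
      int u = adjncy[p];
      if (vis[u] != vepoch) {
        vis[u] = vepoch;  // temporarily mark to dedupe front
        front.push_back(u);
      }
    }
    for (int u : front) vis[u] = 0;  // unmark (front not yet in ball)
    while (true) {
      if (front.empty()) {
        exhausted = true;
        return false;
      }
      if (induced_components(front) >= 2) return true;
      if ((int)(ball.size() + front.size()) > max_ball) return false;
      for (int u : front) {
        vis[u] = vepoch;
        ball.push_back(u);
      }
      std::vector<int> nf;
      fepoch++;
      for (int v : front)
        for (int p = xadj[v]; p < xadj[v + 1]; p++) {
          int u = adjncy[p];
          if (vis[u] != vepoch && fmark[u] != fepoch) {
            fmark[u] = fepoch;
            nf.push_back(u);
          }
        }
      front.swap(nf);
    }
  }

  // greedy minimization, peeling outermost (latest-added) vertices first
  void minimize(std::vector<int>& S) {
    for (int i = (int)S.size() - 1; i >= 0; i--) {
      if (S.size() <= 1) break;
      int v = S[i];
      std::vector<int> trial;
      trial.reserve(S.size() - 1);
      for (size_t j = 0; j < S.size(); j++)
        if ((int)j != i) trial.push_back(S[j]);
      if (separates(trial)) S.swap(trial);
    }
  }
};

}  // namespace

// [[Rcpp::export]]
List separator_search_cpp(IntegerVector xadj, IntegerVector adjncy,
                          int seed1, int max_ball, bool minimize) {
  SepCtx ctx(xadj.begin(), adjncy.begin(), xadj.size() - 1);
  std::vector<int> ball;
  bool exhausted = false;
  bool found = ctx.grow(seed1 - 1, max_ball, ball, exhausted);
  if (found && minimize) ctx.minimize(ball);
  IntegerVector verts(ball.size());
  for (size_t i = 0; i < ball.size(); i++) verts[i] = ball[i] + 1;
  return List::create(_["found"] = found, _["exhausted"] = exhausted,
                      _["vertices"] = verts);
}

// Full separator sweep with interleaved greedy packing: vertices are visited
// in ascending id order; vertices already covered by an accepted separator
// are skipped; a found (minimized) separator is accepted iff vertex-disjoint
// from all accepted ones.  Returns the separator id per vertex (0 = none).
// [[Rcpp::export]]
List local_separators_cpp(IntegerVector xadj, IntegerVector adjncy,
                          int max_ball) {
  const int n = xadj.size() - 1;
  SepCtx ctx(xadj.begin(), adjncy.begin(), n);
  IntegerVector sep_id(n, 0);
  int nsep = 0;
  std::vector<int> ball;
  for (int v = 0; v < n; v++) {
    if (sep_id[v]) continue;
    bool exhausted = false;
    if (!ctx.grow(v, max_ball, ball, exhausted)) continue;
    ctx.minimize(ball);
    bool clash = false;
    for (int u : ball)
      if (sep_id[u]) { clash = true; break; }
    if (clash) continue;
    nsep++;
    for (int u : ball) sep_id[u] = nsep;
  }
  return List::create(_["sep_id"] = sep_id, _["n_sep"] = nsep);
}
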