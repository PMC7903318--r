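// Low-level 3D image primitives shared by the filtering, segmentation and
// topology layers. Volumes are passed as flat numeric/integer vectors in R's
// column-major layout with dims = c(n1, n2, n3); axis 1 is the depth axis.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstring>
#include <queue>
#include <limits>

using namespace Rcpp;

static inline long idx3(long i, long j, long k, long n1, long n2) {
  return i + n1 * (j + n2 * k);
}

// ---------------------------------------------------------------------------
// Separable correlation along one axis with half-sample symmetric reflection
// at the borders (index -1 maps to 0, index L maps to L-1).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_filter_axis(NumericVector vol, IntegerVector dims,
                              NumericVector kernel, int axis) {
  const long n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const int L = dims[axis];
  const int K = kernel.size();
  const int half = K / 2;
  NumericVector out(vol.size());

  long stride[3] = {1, n1, n1 * n2};
  int others[2], c = 0;
  for (int d = 0; d < 3; ++d) if (d != axis) others[c++] = d;
  const long m1 = dims[others[0]], m2 = dims[others[1]];
  const long s1 = stride[others[0]], s2 = stride[others[1]];
  const long sa = stride[axis];

  std::vector<double> line(L), res(L);
  for (long b = 0; b < m2; ++b) {
    for (long a = 0; a < m1; ++a) {
      const long base = a * s1 + b * s2;
      for (int i = 0; i < L; ++i) line[i] = vol[base + (long)i * sa];
      for (int i = 0; i < L; ++i) {
        double acc = 0.0;
        for (int t = 0; t < K; ++t) {
          int p = i + t - half;
          if (p < 0) p = -p - 1;
          else if (p >= L) p = 2 * L - p - 1;
          if (p < 0) p = 0;
          if (p >= L) p = L - 1;
          acc += kernel[t] * line[p];
        }
        res[i] = acc;
      }
      for (int i = 0; i < L; ++i) out[base + (long)i * sa] = res[i];
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Eigenvalues of per-voxel symmetric 3x3 matrices by cyclic Jacobi rotation,
// sorted by ascending magnitude. Accurate to machine precision relative to
// the spectral norm, which matters for the near-zero axial eigenvalue of
// tubular structures.
// ---------------------------------------------------------------------------

static void jacobi3(double a[3][3], double w[3]) {
  for (int sweep = 0; sweep < 30; ++sweep) {
    double off = std::fabs(a[0][1]) + std::fabs(a[0][2]) + std::fabs(a[1][2]);
    if (off == 0.0) break;
    double scale = 0.0;
    for (int i = 0; i < 3; ++i)
      for (int j = i; j < 3; ++j) scale = std::max(scale, std::fabs(a[i][j]));
    if (scale == 0.0 || off <= 1e-15 * scale) break;
    for (int p = 0; p < 2; ++p) {
      for (int q = p + 1; q < 3; ++q) {
        double apq = a[p][q];
        if (std::fabs(apq) <= 1e-18 * scale) continue;
        double theta = (a[q][q] - a[p][p]) / (2.0 * apq);
        double t = (theta >= 0 ? 1.0 : -1.0) /
                   (std::fabs(theta) + std::sqrt(theta * theta + 1.0));
        double cs = 1.0 / std::sqrt(t * t + 1.0);
        double sn = t * cs;
        double app = a[p][p], aqq = a[q][q];
        a[p][p] = app - t * apq;
        a[q][q] = aqq + t * apq;
        a[p][q] = 0.0;
        int r = 3 - p - q;  // remaining index
        double arp = a[std::min(r, p)][std::max(r, p)];
        double arq = a[std::min(r, q)][std::max(r, q)];
        a[std::min(r, p)][std::max(r, p)] = cs * arp - sn * arq;
        a[std::min(r, q)][std::max(r, q)] = sn * arp + cs * arq;
      }
    }
  }
  w[0] = a[0][0]; w[1] = a[1][1]; w[2] = a[2][2];
  // sort by |.| ascending
  for (int i = 0; i < 2; ++i)
    for (int j = 0; j < 2 - i; ++j)
      if (std::fabs(w[j]) > std::fabs(w[j + 1])) std::swap(w[j], w[j + 1]);
}

// [[Rcpp::export]]
NumericMatrix cpp_eig3_sym(NumericVector hxx, NumericVector hyy,
                           NumericVector hzz, NumericVector hxy,
                           NumericVector hxz, NumericVector hyz) {
  const long n = hxx.size();
  NumericMatrix out(n, 3);
  double a[3][3], w[3];
  for (long v = 0; v < n; ++v) {
    a[0][0] = hxx[v]; a[1][1] = hyy[v]; a[2][2] = hzz[v];
    a[0][1] = hxy[v]; a[0][2] = hxz[v]; a[1][2] = hyz[v];
    a[1][0] = a[0][1]; a[2][0] = a[0][2]; a[2][1] = a[1][2];
    jacobi3(a, w);
    out(v, 0) = w[0]; out(v, 1) = w[1]; out(v, 2) = w[2];
  }
  return out;
}

// ---------------------------------------------------------------------------
// Connected-component labelling (6/18/26 neighbourhood) by BFS.
// ---------------------------------------------------------------------------

static int build_offsets(int connectivity, int off[26][3]) {
  int c = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        off[c][0] = dx; off[c][1] = dy; off[c][2] = dz;
        ++c;
      }
  return c;
}

// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dims,
                          int connectivity) {
  const long n1 = dims[0], n2 = dims[1], n3 = dims[2];
  IntegerVector lab(mask.size(), 0);
  int off[26][3];
  const int noff = build_offsets(connectivity, off);
  int next = 0;
  std::vector<long> stack;
  for (long k = 0; k < n3; ++k)
    for (long j = 0; j < n2; ++j)
      for (long i = 0; i < n1; ++i) {
        long v = idx3(i, j, k, n1, n2);
        if (!mask[v] || lab[v]) continue;
        lab[v] = ++next;
        stack.clear();
        stack.push_back(v);
        while (!stack.empty()) {
          long cur = stack.back(); stack.pop_back();
          long ci = cur % n1, cj = (cur / n1) % n2, ck = cur / (n1 * n2);
          for (int t = 0; t < noff; ++t) {
            long ni = ci + off[t][0], nj = cj + off[t][1], nk = ck + off[t][2];
            if (ni < 0 || nj < 0 || nk < 0 || ni >= n1 || nj >= n2 || nk >= n3)
              continue;
            long nv = idx3(ni, nj, nk, n1, n2);
            if (mask[nv] && !lab[nv]) { lab[nv] = next; stack.push_back(nv); }
          }
        }
      }
  return lab;
}

// ---------------------------------------------------------------------------
// Exact squared Euclidean distance transform (distance of each foreground
// voxel to the nearest background voxel), separable lower-envelope method.
// Voxels outside the volume count as background.
// ---------------------------------------------------------------------------

static void dt1d(std::vector<double>& f, int n) {
  static const double INF = std::numeric_limits<double>::infinity();
  std::vector<int> v(n);
  std::vector<double> z(n + 1), d(n);
  int k = 0;
  v[0] = 0; z[0] = -INF; z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q; z[k] = s; z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (q - v[k]) * (double)(q - v[k]) + f[v[k]];
  }
  for (int q = 0; q < n; ++q) f[q] = d[q];
}

// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dims,
                         bool outside_is_background) {
  const long n1 = dims[0], n2 = dims[1], n3 = dims[2];
  // large finite seed: keeps the lower-envelope arithmetic well defined on
  // lines that contain no background at all
  const double BIG = 2.0 * (double)(n1 * n1 + n2 * n2 + n3 * n3) + 1.0;
  NumericVector g(mask.size());
  for (long v = 0; v < (long)mask.size(); ++v) g[v] = mask[v] ? BIG : 0.0;

  // pass along axis 1; seed a virtual background just outside if requested
  std::vector<double> line;
  for (int axis = 0; axis < 3; ++axis) {
    long stride[3] = {1, n1, n1 * n2};
    int others[2], c = 0;
    for (int d = 0; d < 3; ++d) if (d != axis) others[c++] = d;
    const long m1 = dims[others[0]], m2 = dims[others[1]];
    const long s1 = stride[others[0]], s2 = stride[others[1]];
    const long sa = stride[axis];
    const int L = dims[axis];
    const int pad = outside_is_background ? 1 : 0;
    line.assign(L + 2 * pad, 0.0);
    for (long b = 0; b < m2; ++b)
      for (long a = 0; a < m1; ++a) {
        const long base = a * s1 + b * s2;
        if (pad) { line[0] = 0.0; line[L + 1] = 0.0; }
        for (int i = 0; i < L; ++i) line[i + pad] = g[base + (long)i * sa];
        dt1d(line, L + 2 * pad);
        for (int i = 0; i < L; ++i) g[base + (long)i * sa] = line[i + pad];
      }
  }
  return g;
}

// ---------------------------------------------------------------------------
// Sum of a k^3 box around every voxel (zero padding outside), via three
// 1D running sums. Used for the binary majority-vote median filter.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_boxsum(NumericVector vol, IntegerVector dims, int k) {
  const int half = k / 2;
  NumericVector cur = clone(vol);
  const long n1 = dims[0], n2 = dims[1], n3 = dims[2];
  long stride[3] = {1, n1, n1 * n2};
  for (int axis = 0; axis < 3; ++axis) {
    NumericVector nxt(cur.size());
    int others[2], c = 0;
    for (int d = 0; d < 3; ++d) if (d != axis) others[c++] = d;
    const long m1 = dims[others[0]], m2 = dims[others[1]];
    const long s1 = stride[others[0]], s2 = stride[others[1]];
    const long sa = stride[axis];
    const int L = dims[axis];
    std::vector<double> line(L);
    for (long b = 0; b < m2; ++b)
      for (long a = 0; a < m1; ++a) {
        const long base = a * s1 + b * s2;
        for (int i = 0; i < L; ++i) line[i] = cur[base + (long)i * sa];
        double acc = 0.0;
        for (int i = 0; i <= std::min(half - 1, L - 1); ++i) acc += line[i];
        for (int i = 0; i < L; ++i) {
          int add = i + half, rem = i - half - 1;
          if (add < L) acc += line[add];
          if (rem >= 0) acc -= line[rem];
          nxt[base + (long)i * sa] = acc;
        }
      }
    cur = nxt;
  }
  return cur;
}

// ---------------------------------------------------------------------------
// Topology-preserving 3D thinning to a curve skeleton.
//
// A foreground voxel is "simple" (deletable without changing topology) iff
// (a) the foreground restricted to its 26-neighbourhood has exactly one
//     26-connected component, and
// (b) the background restricted to its 18-neighbourhood has exactly one
//     6-connected component containing a face neighbour
// (Bertrand & Malandain characterisation). Curve endpoints (<= 1 foreground
// neighbour) are never removed. Deletion proceeds in six directional
// subiterations (U, D, N, S, E, W) with sequential rechecking, which keeps
// the skeleton centred.
// ---------------------------------------------------------------------------

namespace thin {

// neighbourhood cell index: (dx,dy,dz) in {-1,0,1}^3 -> 0..26, center = 13
static inline int cell(int dx, int dy, int dz) {
  return (dx + 1) + 3 * (dy + 1) + 9 * (dz + 1);
}

static bool tables_ready = false;
static std::vector<int> adj26[27];   // 26-adjacency between cells (excl. center)
static std::vector<int> adj6[27];    // 6-adjacency between cells, within N18
static bool in_n18[27];
static bool is_face[27];

static void build_tables() {
  int coord[27][3];
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int c = cell(dx, dy, dz);
        coord[c][0] = dx; coord[c][1] = dy; coord[c][2] = dz;
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        in_n18[c] = (c != 13) && (m <= 2);
        is_face[c] = (m == 1);
      }
  for (int a = 0; a < 27; ++a) {
    if (a == 13) continue;
    for (int b = 0; b < 27; ++b) {
      if (b == 13 || b == a) continue;
      int dx = std::abs(coord[a][0] - coord[b][0]);
      int dy = std::abs(coord[a][1] - coord[b][1]);
      int dz = std::abs(coord[a][2] - coord[b][2]);
      int cheb = std::max(dx, std::max(dy, dz));
      int man = dx + dy + dz;
      if (cheb == 1) adj26[a].push_back(b);
      if (man == 1 && in_n18[a] && in_n18[b]) adj6[a].push_back(b);
    }
  }
  tables_ready = true;
}

// nb[27]: foreground flags of the neighbourhood (center included)
static bool is_simple(const bool nb[27]) {
  // (a) exactly one 26-component of foreground among the 26 neighbours
  bool seen[27] = {false};
  int comp = 0;
  int stack[27], top;
  for (int c = 0; c < 27; ++c) {
    if (c == 13 || !nb[c] || seen[c]) continue;
    if (++comp > 1) return false;
    top = 0; stack[top++] = c; seen[c] = true;
    while (top) {
      int cur = stack[--top];
      for (size_t t = 0; t < adj26[cur].size(); ++t) {
        int nx = adj26[cur][t];
        if (nb[nx] && !seen[nx]) { seen[nx] = true; stack[top++] = nx; }
      }
    }
  }
  if (comp != 1) return false;
  // (b) exactly one 6-component of background in N18 touching a face cell
  std::memset(seen, 0, sizeof(seen));
  comp = 0;
  for (int c = 0; c < 27; ++c) {
    if (!is_face[c] || nb[c] || seen[c]) continue;
    ++comp;
    if (comp > 1) return false;
    top = 0; stack[top++] = c; seen[c] = true;
    while (top) {
      int cur = stack[--top];
      for (size_t t = 0; t < adj6[cur].size(); ++t) {
        int nx = adj6[cur][t];
        if (!nb[nx] && !seen[nx]) { seen[nx] = true; stack[top++] = nx; }
      }
    }
  }
  return comp == 1;
}

}  // namespace thin

// [[Rcpp::export]]
LogicalVector cpp_skeletonize3d(LogicalVector mask, IntegerVector dims) {
  if (!thin::tables_ready) thin::build_tables();
  const long n1 = dims[0], n2 = dims[1], n3 = dims[2];
  std::vector<char> fg(mask.size());
  for (long v = 0; v < (long)mask.size(); ++v) fg[v] = mask[v] ? 1 : 0;

  // direction offsets: the border test looks at the 6 face neighbours
  const int dir[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};

  auto get = [&](long i, long j, long k) -> char {
    if (i < 0 || j < 0 || k < 0 || i >= n1 || j >= n2 || k >= n3) return 0;
    return fg[idx3(i, j, k, n1, n2)];
  };
  auto fill_nb = [&](long i, long j, long k, bool nb[27]) {
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx)
          nb[thin::cell(dx, dy, dz)] = get(i + dx, j + dy, k + dz) != 0;
  };
  auto n26_count = [&](const bool nb[27]) {
    int c = 0;
    for (int t = 0; t < 27; ++t) if (t != 13 && nb[t]) ++c;
    return c;
  };

  std::vector<long> cand;
  bool changed = true;
  bool nb[27];
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      cand.clear();
      for (long k = 0; k < n3; ++k)
        for (long j = 0; j < n2; ++j)
          for (long i = 0; i < n1; ++i) {
            long v = idx3(i, j, k, n1, n2);
            if (!fg[v]) continue;
            if (get(i + dir[d][0], j + dir[d][1], k + dir[d][2])) continue;
            fill_nb(i, j, k, nb);
            int nn = n26_count(nb);
            if (nn <= 1) continue;  // endpoint or isolated
            if (thin::is_simple(nb)) cand.push_back(v);
          }
      // sequential re-check: earlier deletions may make later ones unsafe
      for (size_t t = 0; t < cand.size(); ++t) {
        long v = cand[t];
        long i = v % n1, j = (v / n1) % n2, k = v / (n1 * n2);
        fill_nb(i, j, k, nb);
        int nn = n26_count(nb);
        if (nn <= 1) continue;
        if (thin::is_simple(nb)) { fg[v] = 0; changed = true; }
      }
    }
  }

  LogicalVector out(mask.size());
  for (long v = 0; v < (long)mask.size(); ++v) out[v] = fg[v] != 0;
  return out;
}

// ---------------------------------------------------------------------------
// Count foreground 26-neighbours of every voxel (for graph construction).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_neighbor_count26(LogicalVector mask, IntegerVector dims) {
  const long n1 = dims[0], n2 = dims[1], n3 = dims[2];
  IntegerVector out(mask.size(), 0);
  for (long k = 0; k < n3; ++k)
    for (long j = 0; j < n2; ++j)
      for (long i = 0; i < n1; ++i) {
        long v = idx3(i, j, k, n1, n2);
        if (!mask[v]) continue;
        int c = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (!dx && !dy && !dz) continue;
              long ni = i + dx, nj = j + dy, nk = k + dz;
              if (ni < 0 || nj < 0 || nk < 0 || ni >= n1 || nj >= n2 ||
                  nk >= n3)
                continue;
              if (mask[idx3(ni, nj, nk, n1, n2)]) ++c;
            }
        out[v] = c;
      }
  return out;
}

// ---------------------------------------------------------------------------
// Paint a chain of spheres (densely resampled tube centerline) into a
// coverage volume: coverage = max(coverage, clamp(r + 0.5 - dist, 0, 1)).
// pts are 0-based voxel coordinates (axis order matching dims).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_paint_tube(NumericVector coverage, IntegerVector dims,
                             NumericMatrix pts, NumericVector radii) {
  const long n1 = dims[0], n2 = dims[1], n3 = dims[2];
  NumericVector cov = coverage;  // modified in place by design
  for (long p = 0; p < pts.nrow(); ++p) {
    const double cx = pts(p, 0), cy = pts(p, 1), cz = pts(p, 2);
    const double r = radii[p];
    const double reach = r + 1.0;
    const long i0 = std::max(0L, (long)std::floor(cx - reach));
    const long i1 = std::min(n1 - 1, (long)std::ceil(cx + reach));
    const long j0 = std::max(0L, (long)std::floor(cy - reach));
    const long j1 = std::min(n2 - 1, (long)std::ceil(cy + reach));
    const long k0 = std::max(0L, (long)std::floor(cz - reach));
    const long k1 = std::min(n3 - 1, (long)std::ceil(cz + reach));
    for (long k = k0; k <= k1; ++k)
      for (long j = j0; j <= j1; ++j)
        for (long i = i0; i <= i1; ++i) {
          double dx = i - cx, dy = j - cy, dz = k - cz;
          double dist = std::sqrt(dx * dx + dy * dy + dz * dz);
          double val = r + 0.5 - dist;
          if (val <= 0) continue;
          if (val > 1) val = 1;
          long v = idx3(i, j, k, n1, n2);
          if (val > cov[v]) cov[v] = val;
        }
  }
  return cov;
}
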