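#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Volumes are passed as flat vectors in R column-major order for a (Z, Y, X)
// array: index = z + Z * (y + Y * x), all 0-based.

static inline int vidx(int z, int y, int x, int Z, int Y) {
  return z + Z * (y + Y * x);
}

// neighbor offsets for 6 / 18 / 26 connectivity
static void neighbor_offsets(int connectivity, std::vector<int>& dz,
                             std::vector<int>& dy, std::vector<int>& dx) {
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        int m = std::abs(a) + std::abs(b) + std::abs(c);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        dz.push_back(a); dy.push_back(b); dx.push_back(c);
      }
}

// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  const int Z = dims[0], Y = dims[1], X = dims[2];
  const int n = Z * Y * X;
  IntegerVector labels(n, 0);
  std::vector<int> dz, dy, dx;
  neighbor_offsets(connectivity, dz, dy, dx);
  const int nn = (int) dz.size();
  std::vector<int> stack;
  int current = 0;
  for (int x = 0; x < X; ++x)
    for (int y = 0; y < Y; ++y)
      for (int z = 0; z < Z; ++z) {
        int i = vidx(z, y, x, Z, Y);
        if (!mask[i] || labels[i] != 0) continue;
        ++current;
        labels[i] = current;
        stack.clear();
        stack.push_back(i);
        while (!stack.empty()) {
          int j = stack.back(); stack.pop_back();
          int zz = j % Z, rest = j / Z;
          int yy = rest % Y, xx = rest / Y;
          for (int k = 0; k < nn; ++k) {
            int z2 = zz + dz[k], y2 = yy + dy[k], x2 = xx + dx[k];
            if (z2 < 0 || z2 >= Z || y2 < 0 || y2 >= Y || x2 < 0 || x2 >= X)
              continue;
            int j2 = vidx(z2, y2, x2, Z, Y);
            if (mask[j2] && labels[j2] == 0) {
              labels[j2] = current;
              stack.push_back(j2);
            }
          }
        }
      }
  labels.attr("dim") = dims;
  return labels;
}

// --- simple-point machinery for medial-axis thinning ---------------------
//
// A foreground voxel is "simple" (deletable without changing topology) iff
//   (a) the foreground restricted to its 26-neighborhood (center excluded)
//       has exactly one 26-connected component, and
//   (b) the background restricted to its 18-neighborhood has exactly one
//       6-connected component that is 6-adjacent to the voxel.
// This is the classic characterization for (26, 6) digital topology.

static int cube_coord[27][3];   // (dz,dy,dx) for local cube cells
static bool cube_init_done = false;

static void init_cube() {
  if (cube_init_done) return;
  int k = 0;
  for (int c = -1; c <= 1; ++c)
    for (int b = -1; b <= 1; ++b)
      for (int a = -1; a <= 1; ++a) {
        cube_coord[k][0] = a; cube_coord[k][1] = b; cube_coord[k][2] = c;
        ++k;
      }
  cube_init_done = true;
}

static inline int cube_index(int a, int b, int c) {
  return (a + 1) + 3 * (b + 1) + 9 * (c + 1);
}

static bool is_simple(const bool cube[27]) {
  // cube[] holds the 3x3x3 occupancy; center is cube_index(0,0,0) == 13
  init_cube();
  // (a) one 26-component of foreground in N26* (exclude center)
  bool seen[27];
  int comp = 0;
  for (int i = 0; i < 27; ++i) seen[i] = false;
  int nfg = 0;
  for (int i = 0; i < 27; ++i) if (i != 13 && cube[i]) ++nfg;
  if (nfg == 0) return false;  // isolated point, never deleted
  for (int i = 0; i < 27; ++i) {
    if (i == 13 || !cube[i] || seen[i]) continue;
    ++comp;
    if (comp > 1) return false;
    int stack[27], sp = 0;
    stack[sp++] = i; seen[i] = true;
    while (sp > 0) {
      int j = stack[--sp];
      for (int k = 0; k < 27; ++k) {
        if (k == 13 || k == j || !cube[k] || seen[k]) continue;
        if (std::abs(cube_coord[k][0] - cube_coord[j][0]) <= 1 &&
            std::abs(cube_coord[k][1] - cube_coord[j][1]) <= 1 &&
            std::abs(cube_coord[k][2] - cube_coord[j][2]) <= 1) {
          seen[k] = true;
          stack[sp++] = k;
        }
      }
    }
  }
  if (comp != 1) return false;
  // (b) one 6-component of background within N18 touching a face neighbor
  for (int i = 0; i < 27; ++i) seen[i] = false;
  comp = 0;
  for (int i = 0; i < 27; ++i) {
    int m = std::abs(cube_coord[i][0]) + std::abs(cube_coord[i][1]) +
            std::abs(cube_coord[i][2]);
    if (m == 0 || m == 3) continue;           // N18 only
    if (cube[i] || seen[i]) continue;
    if (m != 1) continue;                     // seed components at face cells
    ++comp;
    if (comp > 1) return false;
    int stack[27], sp = 0;
    stack[sp++] = i; seen[i] = true;
    while (sp > 0) {
      int j = stack[--sp];
      for (int k = 0; k < 27; ++k) {
        int mk = std::abs(cube_coord[k][0]) + std::abs(cube_coord[k][1]) +
                 std::abs(cube_coord[k][2]);
        if (mk == 0 || mk == 3 || cube[k] || seen[k]) continue;
        int d = std::abs(cube_coord[k][0] - cube_coord[j][0]) +
                std::abs(cube_coord[k][1] - cube_coord[j][1]) +
                std::abs(cube_coord[k][2] - cube_coord[j][2]);
        if (d == 1) { seen[k] = true; stack[sp++] = k; }
      }
    }
  }
  return comp == 1;
}

static void fill_cube(const std::vector<char>& vox, int z, int y, int x,
                      int Z, int Y, int X, bool cube[27]) {
  for (int c = -1; c <= 1; ++c)
    for (int b = -1; b <= 1; ++b)
      for (int a = -1; a <= 1; ++a) {
        int z2 = z + a, y2 = y + b, x2 = x + c;
        bool v = false;
        if (z2 >= 0 && z2 < Z && y2 >= 0 && y2 < Y && x2 >= 0 && x2 < X)
          v = vox[vidx(z2, y2, x2, Z, Y)] != 0;
        cube[cube_index(a, b, c)] = v;
      }
}

static int count_fg_neighbors26(const std::vector<char>& vox, int z, int y,
                                int x, int Z, int Y, int X) {
  int cnt = 0;
  for (int c = -1; c <= 1; ++c)
    for (int b = -1; b <= 1; ++b)
      for (int a = -1; a <= 1; ++a) {
        if (a == 0 && b == 0 && c == 0) continue;
        int z2 = z + a, y2 = y + b, x2 = x + c;
        if (z2 < 0 || z2 >= Z || y2 < 0 || y2 >= Y || x2 < 0 || x2 >= X)
          continue;
        if (vox[vidx(z2, y2, x2, Z, Y)]) ++cnt;
      }
  return cnt;
}

// Chamfer (3-4-5) distance transform of a binary volume: two-pass sweep
// with face/edge/corner weights 3/4/5; background voxels have distance 0.
// [[Rcpp::export]]
IntegerVector cpp_chamfer_dt(LogicalVector mask, IntegerVector dims) {
  const int Z = dims[0], Y = dims[1], X = dims[2];
  const int n = Z * Y * X;
  const int BIG = 1 << 29;
  IntegerVector d(n);
  for (int i = 0; i < n; ++i) d[i] = mask[i] ? BIG : 0;
  // forward: neighbors already visited in (z fast, y, x slow) scan order
  for (int x = 0; x < X; ++x)
    for (int y = 0; y < Y; ++y)
      for (int z = 0; z < Z; ++z) {
        int i = vidx(z, y, x, Z, Y);
        if (!mask[i]) continue;
        int best = d[i];
        for (int c = -1; c <= 0; ++c)
          for (int b = -1; b <= 1; ++b)
            for (int a = -1; a <= 1; ++a) {
              if (c == 0 && (b > 0 || (b == 0 && a >= 0))) continue;
              int z2 = z + a, y2 = y + b, x2 = x + c;
              int w = 3 + std::abs(a) + std::abs(b) + std::abs(c) - 1;
              int val;
              if (z2 < 0 || z2 >= Z || y2 < 0 || y2 >= Y || x2 < 0 || x2 >= X)
                val = 0;  // outside counts as background
              else val = d[vidx(z2, y2, x2, Z, Y)];
              if (val + w < best) best = val + w;
            }
        d[i] = best;
      }
  // backward
  for (int x = X - 1; x >= 0; --x)
    for (int y = Y - 1; y >= 0; --y)
      for (int z = Z - 1; z >= 0; --z) {
        int i = vidx(z, y, x, Z, Y);
        if (!mask[i]) continue;
        int best = d[i];
        for (int c = 0; c <= 1; ++c)
          for (int b = -1; b <= 1; ++b)
            for (int a = -1; a <= 1; ++a) {
              if (c == 0 && (b < 0 || (b == 0 && a <= 0))) continue;
              int z2 = z + a, y2 = y + b, x2 = x + c;
              int w = 3 + std::abs(a) + std::abs(b) + std::abs(c) - 1;
              int val;
              if (z2 < 0 || z2 >= Z || y2 < 0 || y2 >= Y || x2 < 0 || x2 >= X)
                val = 0;
              else val = d[vidx(z2, y2, x2, Z, Y)];
              if (val + w < best) best = val + w;
            }
        d[i] = best;
      }
  d.attr("dim") = dims;
  return d;
}

// Subfield-sequential directional thinning. Deletion is restricted per
// sub-iteration to voxels whose face neighbor in the current direction is
// background, and each sub-iteration runs over the eight voxel-parity
// subfields in turn: voxels of one subfield are never 26-adjacent, so
// deletions within a pass are independent and a candidate front cannot
// cascade through a 2-voxel-thick plate (the failure mode that makes plain
// sequential thinning collapse even-width rods). Candidates are re-checked
// at removal time so topology is preserved exactly. `anchor` voxels (e.g.
// the distance-transform ridge) are never deleted; with
// `protect_endpoints`, curve endpoints (exactly one 26-neighbor) and
// isolated voxels are retained.
// [[Rcpp::export]]
LogicalVector cpp_thin_skeleton(LogicalVector mask, IntegerVector dims,
                                LogicalVector anchor,
                                bool protect_endpoints) {
  const int Z = dims[0], Y = dims[1], X = dims[2];
  const int n = Z * Y * X;
  const bool use_anchor = anchor.size() == n;
  std::vector<char> vox(n);
  for (int i = 0; i < n; ++i) vox[i] = mask[i] ? 1 : 0;
  const int dirs[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};
  bool cube[27];
  std::vector<int> cand;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      for (int sf = 0; sf < 8; ++sf) {
        cand.clear();
        for (int x = 0; x < X; ++x)
          for (int y = 0; y < Y; ++y)
            for (int z = 0; z < Z; ++z) {
              if (((z & 1) | ((y & 1) << 1) | ((x & 1) << 2)) != sf) continue;
              int i = vidx(z, y, x, Z, Y);
              if (!vox[i]) continue;
              if (use_anchor && anchor[i]) continue;
              int z2 = z + dirs[d][0], y2 = y + dirs[d][1], x2 = x + dirs[d][2];
              bool border = (z2 < 0 || z2 >= Z || y2 < 0 || y2 >= Y ||
                             x2 < 0 || x2 >= X) ||
                            !vox[vidx(z2, y2, x2, Z, Y)];
              if (!border) continue;
              int nb = count_fg_neighbors26(vox, z, y, x, Z, Y, X);
              if (nb == 0) continue;  // isolated voxel always kept
              if (protect_endpoints && nb == 1) continue;
              fill_cube(vox, z, y, x, Z, Y, X, cube);
              if (is_simple(cube)) cand.push_back(i);
            }
        for (size_t q = 0; q < cand.size(); ++q) {
          int i = cand[q];
          int z = i % Z, rest = i / Z;
          int y = rest % Y, x = rest / Y;
          int nb = count_fg_neighbors26(vox, z, y, x, Z, Y, X);
          if (nb == 0) continue;
          if (protect_endpoints && nb == 1) continue;
          fill_cube(vox, z, y, x, Z, Y, X, cube);
          if (is_simple(cube)) {
            vox[i] = 0;
            changed = true;
          }
        }
      }
    }
  }
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) out[i] = vox[i] != 0;
  out.attr("dim") = dims;
  return out;
}

// 3x3x3 median filter; out-of-bounds neighbors are dropped from the window.
// [[Rcpp::export]]
NumericVector cpp_median_filter3(NumericVector vol, IntegerVector dims) {
  const int Z = dims[0], Y = dims[1], X = dims[2];
  NumericVector out(vol.size());
  std::vector<double> w;
  w.reserve(27);
  for (int x = 0; x < X; ++x)
    for (int y = 0; y < Y; ++y)
      for (int z = 0; z < Z; ++z) {
        w.clear();
        for (int c = -1; c <= 1; ++c)
          for (int b = -1; b <= 1; ++b)
            for (int a = -1; a <= 1; ++a) {
              int z2 = z + a, y2 = y + b, x2 = x + c;
              if (z2 < 0 || z2 >= Z || y2 < 0 || y2 >= Y || x2 < 0 || x2 >= X)
                continue;
              w.push_back(vol[vidx(z2, y2, x2, Z, Y)]);
            }
        size_t m = w.size() / 2;
        std::nth_element(w.begin(), w.begin() + m, w.end());
        double med = w[m];
        if (w.size() % 2 == 0) {
          std::nth_element(w.begin(), w.begin() + m - 1, w.begin() + m);
          med = 0.5 * (med + w[m - 1]);
        }
        out[vidx(z, y, x, Z, Y)] = med;
      }
  out.attr("dim") = dims;
  return out;
}

// Eigenvalues of symmetric 3x3 matrices [[hxx hxy hxz],[hxy hyy hyz],
// [hxz hyz hzz]] per voxel, returned sorted by increasing |lambda|.
// Uses the trigonometric closed form for symmetric 3x3 matrices.
// [[Rcpp::export]]
NumericMatrix cpp_eig3_sym(NumericVector hxx, NumericVector hyy,
                           NumericVector hzz, NumericVector hxy,
                           NumericVector hxz, NumericVector hyz) {
  const int n = hxx.size();
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    double a = hxx[i], b = hyy[i], c = hzz[i];
    double d = hxy[i], e = hyz[i], f = hxz[i];
    double p1 = d * d + e * e + f * f;
    double l1, l2, l3;
    if (p1 < 1e-300) {
      l1 = a; l2 = b; l3 = c;
    } else {
      double q = (a + b + c) / 3.0;
      double p2 = (a - q) * (a - q) + (b - q) * (b - q) + (c - q) * (c - q) +
                  2.0 * p1;
      double p = std::sqrt(p2 / 6.0);
      // r = det((A - q I) / p) / 2
      double B11 = (a - q) / p, B22 = (b - q) / p, B33 = (c - q) / p;
      double B12 = d / p, B23 = e / p, B13 = f / p;
      double r = (B11 * (B22 * B33 - B23 * B23) -
                  B12 * (B12 * B33 - B23 * B13) +
                  B13 * (B12 * B23 - B22 * B13)) / 2.0;
      if (r < -1.0) r = -1.0;
      if (r > 1.0) r = 1.0;
      double phi = std::acos(r) / 3.0;
      l1 = q + 2.0 * p * std::cos(phi);
      l3 = q + 2.0 * p * std::cos(phi + 2.0 * M_PI / 3.0);
      l2 = 3.0 * q - l1 - l3;
    }
    double v[3] = {l1, l2, l3};
    std::sort(v, v + 3, [](double x, double y) {
      return std::abs(x) < std::abs(y);
    });
    out(i, 0) = v[0]; out(i, 1) = v[1]; out(i, 2) = v[2];
  }
  return out;
}
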