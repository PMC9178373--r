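#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static const double BIG = 1e30;

// 1D squared-distance transform (lower envelope of parabolas).
// f: input costs, d: output, v/z: work arrays of size n and n+1.
static void dt1d(std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &z, int n) {
  int k = 0;
  v[0] = 0;
  z[0] = -BIG;
  z[1] = BIG;
  for (int q = 1; q < n; q++) {
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      k--;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = BIG;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    double dq = (double)(q - v[k]);
    d[q] = dq * dq + f[v[k]];
  }
}

// Squared Euclidean distance (voxel units) from every foreground voxel to the
// nearest background voxel. Background voxels get 0. The volume boundary is
// treated as a continuation of the foreground (no implicit background ring),
// so a phase spanning the full extent behaves like a periodic/padded slab.
// [[Rcpp::export]]
NumericVector sq_edt_cpp(LogicalVector fg, IntegerVector dims) {
  int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  std::vector<double> g(n);
  for (R_xlen_t i = 0; i < n; i++) g[i] = fg[i] ? BIG : 0.0;

  int nmax = std::max(n1, std::max(n2, n3));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // axis 1 (stride 1)
  for (int k = 0; k < n3; k++)
    for (int j = 0; j < n2; j++) {
      R_xlen_t base = (R_xlen_t)n1 * (j + (R_xlen_t)n2 * k);
      for (int i = 0; i < n1; i++) f[i] = g[base + i];
      dt1d(f, d, v, z, n1);
      for (int i = 0; i < n1; i++) g[base + i] = d[i];
    }
  // axis 2 (stride n1)
  for (int k = 0; k < n3; k++)
    for (int i = 0; i < n1; i++) {
      R_xlen_t base = (R_xlen_t)i + (R_xlen_t)n1 * n2 * k;
      for (int j = 0; j < n2; j++) f[j] = g[base + (R_xlen_t)n1 * j];
      dt1d(f, d, v, z, n2);
      for (int j = 0; j < n2; j++) g[base + (R_xlen_t)n1 * j] = d[j];
    }
  // axis 3 (stride n1*n2)
  R_xlen_t s3 = (R_xlen_t)n1 * n2;
  for (int j = 0; j < n2; j++)
    for (int i = 0; i < n1; i++) {
      R_xlen_t base = (R_xlen_t)i + (R_xlen_t)n1 * j;
      for (int k = 0; k < n3; k++) f[k] = g[base + s3 * k];
      dt1d(f, d, v, z, n3);
      for (int k = 0; k < n3; k++) g[base + s3 * k] = d[k];
    }

  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; i++) out[i] = (g[i] >= BIG) ? R_PosInf : g[i];
  return out;
}

struct RidgePt {
  R_xlen_t idx;
  double r;
};

// Sphere-fitting local thickness (maximal inscribed spheres).
// For every foreground voxel: diameter (in voxel units) of the largest sphere
// fully contained in the phase that covers the voxel. Computed as
// EDT -> distance ridge (spheres not contained in a neighbour's sphere) ->
// sphere coverage propagation, painting largest spheres first.
// The reported diameter uses a parity-aware medial-surface rule: a ridge
// voxel whose equal-radius twin lies across the medial surface (the axis
// along which the EDT drops fastest) marks a surface passing between voxel
// layers, so the diameter is 2r there and 2r - 1 otherwise. Slabs of even
// and odd voxel thickness both map to their exact thickness.
// [[Rcpp::export]]
NumericVector local_thickness_cpp(LogicalVector fg, IntegerVector dims) {
  int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  NumericVector ed = sq_edt_cpp(fg, dims);
  std::vector<double> r(n);
  for (R_xlen_t i = 0; i < n; i++)
    r[i] = (ed[i] == R_PosInf) ? BIG : std::sqrt(ed[i]);

  const double eps = 1e-9;
  std::vector<RidgePt> ridge;
  for (int k = 0; k < n3; k++)
    for (int j = 0; j < n2; j++)
      for (int i = 0; i < n1; i++) {
        R_xlen_t idx = (R_xlen_t)i + (R_xlen_t)n1 * (j + (R_xlen_t)n2 * k);
        if (!fg[idx]) continue;
        double rp = r[idx];
        bool redundant = false;
        for (int dk = -1; dk <= 1 && !redundant; dk++)
          for (int dj = -1; dj <= 1 && !redundant; dj++)
            for (int di = -1; di <= 1 && !redundant; di++) {
              if (di == 0 && dj == 0 && dk == 0) continue;
              int ii = i + di, jj = j + dj, kk = k + dk;
              if (ii < 0 || ii >= n1 || jj < 0 || jj >= n2 || kk < 0 || kk >= n3)
                continue;
              R_xlen_t qi =
                  (R_xlen_t)ii + (R_xlen_t)n1 * (jj + (R_xlen_t)n2 * kk);
              if (!fg[qi]) continue;
              double dd = std::sqrt((double)(di * di + dj * dj + dk * dk));
              if (r[qi] >= rp + dd - eps) redundant = true;
            }
        if (!redundant) ridge.push_back({idx, rp});
      }

  std::sort(ridge.begin(), ridge.end(),
            [](const RidgePt &a, const RidgePt &b) { return a.r > b.r; });

  NumericVector out(n);  // zero-initialised
  for (const RidgePt &p : ridge) {
    double ra = std::max(p.r - 0.5, 0.5);
    int ci = (int)(p.idx % n1);
    int cj = (int)((p.idx / n1) % n2);
    int ck = (int)(p.idx / ((R_xlen_t)n1 * n2));
    // parity rule: along the axis where the radius falls off fastest
    // (toward the background), an equal-radius twin means the medial
    // surface lies between voxel layers
    double best_min = BIG, best_max = -1.0;
    const int axi[3] = {1, 0, 0}, axj[3] = {0, 1, 0}, axk[3] = {0, 0, 1};
    for (int a = 0; a < 3; a++) {
      // a neighbour outside the volume continues the phase (same convention
      // as the EDT), so it never bounds the sphere
      double rm = BIG, rp2 = BIG;
      int i1 = ci - axi[a], j1 = cj - axj[a], k1 = ck - axk[a];
      int i2 = ci + axi[a], j2 = cj + axj[a], k2 = ck + axk[a];
      if (i1 >= 0 && j1 >= 0 && k1 >= 0 && i1 < n1 && j1 < n2 && k1 < n3) {
        R_xlen_t q = (R_xlen_t)i1 + (R_xlen_t)n1 * (j1 + (R_xlen_t)n2 * k1);
        rm = fg[q] ? r[q] : 0.0;
      }
      if (i2 < n1 && j2 < n2 && k2 < n3 && i2 >= 0 && j2 >= 0 && k2 >= 0) {
        R_xlen_t q = (R_xlen_t)i2 + (R_xlen_t)n1 * (j2 + (R_xlen_t)n2 * k2);
        rp2 = fg[q] ? r[q] : 0.0;
      }
      double mn = std::min(rm, rp2), mx = std::max(rm, rp2);
      if (mn < best_min) {
        best_min = mn;
        best_max = mx;
      }
    }
    double th = (best_max >= p.r - 1e-6) ? 2.0 * p.r : 2.0 * p.r - 1.0;
    if (th < 1.0) th = 1.0;
    int R = (int)std::floor(ra + eps);
    double ra2 = ra * ra + eps;
    for (int dk = -R; dk <= R; dk++) {
      int kk = ck + dk;
      if (kk < 0 || kk >= n3) continue;
      for (int dj = -R; dj <= R; dj++) {
        int jj = cj + dj;
        if (jj < 0 || jj >= n2) continue;
        double d2p = (double)dk * dk + (double)dj * dj;
        if (d2p > ra2) continue;
        R_xlen_t rowbase = (R_xlen_t)n1 * (jj + (R_xlen_t)n2 * kk);
        for (int di = -R; di <= R; di++) {
          int ii = ci + di;
          if (ii < 0 || ii >= n1) continue;
          if (d2p + (double)di * di > ra2) continue;
          R_xlen_t vi = rowbase + ii;
          if (fg[vi] && out[vi] == 0.0) out[vi] = th;
        }
      }
    }
  }
  // safety net: any foreground voxel missed by ridge coverage falls back to
  // its own inscribed sphere
  for (R_xlen_t i = 0; i < n; i++)
    if (fg[i] && out[i] == 0.0) out[i] = std::max(2.0 * r[i] - 0.5, 1.0);
  return out;
}
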