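#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Directional mean-intercept-length scan.
//
// For each direction (unit row of `dirs`), a family of parallel test lines is
// cast through the spherical VOI of radius `radius` (voxel units) centred at
// `center` (0-based continuous voxel coordinates). The sampling contract,
// mirrored exactly by the brute-force R oracle used in the tests:
//   * basis: e = unit axis with the smallest |direction component|
//     (ties: earlier axis), u = normalize(cross(dir, e)), v = cross(dir, u);
//   * line offsets a = ia*line_spacing, b = ib*line_spacing for integer
//     ia, ib with a^2 + b^2 <= radius^2;
//   * samples at s = m*step for integer m with |m*step| <= half-chord;
//   * a sample maps to the voxel floor(p + 0.5) on each axis; samples outside
//     the volume or outside `mask` are out-of-phase;
//   * a crossing is a marrow->bone transition between two consecutive
//     in-mask samples;
//   * a line contributes only if its in-mask length (samples * step) is at
//     least `min_len` voxels.
// Returns a matrix with one row per direction: total in-mask test-line
// length (voxel units) and number of crossings.
// [[Rcpp::export]]
NumericMatrix mil_scan_cpp(IntegerVector bone, IntegerVector mask,
                           IntegerVector dims, NumericVector center,
                           double radius, NumericMatrix dirs,
                           double line_spacing, double step, double min_len) {
  int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  int nd = dirs.nrow();
  NumericMatrix out(nd, 2);
  int K = (int)std::floor(radius / line_spacing);

  for (int di = 0; di < nd; di++) {
    double wx = dirs(di, 0), wy = dirs(di, 1), wz = dirs(di, 2);
    double ax = std::fabs(wx), ay = std::fabs(wy), az = std::fabs(wz);
    double ex = 0, ey = 0, ez = 0;
    if (ax <= ay && ax <= az)
      ex = 1;
    else if (ay <= az)
      ey = 1;
    else
      ez = 1;
    double ux = wy * ez - wz * ey;
    double uy = wz * ex - wx * ez;
    double uz = wx * ey - wy * ex;
    double un = std::sqrt(ux * ux + uy * uy + uz * uz);
    ux /= un;
    uy /= un;
    uz /= un;
    double vx = wy * uz - wz * uy;
    double vy = wz * ux - wx * uz;
    double vz = wx * uy - wy * ux;

    double totlen = 0.0, totcross = 0.0;
    for (int ia = -K; ia <= K; ia++) {
      for (int ib = -K; ib <= K; ib++) {
        double a = ia * line_spacing, b = ib * line_spacing;
        double rho2 = a * a + b * b;
        if (rho2 > radius * radius) continue;
        double L = std::sqrt(radius * radius - rho2);
        int M = (int)std::floor(L / step);
        double bx = center[0] + a * ux + b * vx;
        double by = center[1] + a * uy + b * vy;
        double bz = center[2] + a * uz + b * vz;
        int nin = 0, cr = 0;
        int prev = -1;
        bool prev_in = false;
        for (int m = -M; m <= M; m++) {
          double px = bx + m * step * wx;
          double py = by + m * step * wy;
          double pz = bz + m * step * wz;
          int i = (int)std::floor(px + 0.5);
          int j = (int)std::floor(py + 0.5);
          int k = (int)std::floor(pz + 0.5);
          bool inm = false;
          int bv = 0;
          if (i >= 0 && i < n1 && j >= 0 && j < n2 && k >= 0 && k < n3) {
            R_xlen_t idx = (R_xlen_t)i + (R_xlen_t)n1 * (j + (R_xlen_t)n2 * k);
            if (mask[idx] != 0) {
              inm = true;
              bv = bone[idx] != 0 ? 1 : 0;
            }
          }
          if (inm) {
            if (prev_in && prev == 0 && bv == 1) cr++;
            nin++;
            prev = bv;
            prev_in = true;
          } else {
            prev_in = false;
            prev = -1;
          }
        }
        if (nin * step >= min_len) {
          totlen += nin * step;
          totcross += cr;
        }
      }
    }
    out(di, 0) = totlen;
    out(di, 1) = totcross;
  }
  return out;
}

// Bone and total voxel counts inside a spherical VOI intersected with a mask.
// [[Rcpp::export]]
NumericVector voi_counts_cpp(IntegerVector bone, IntegerVector mask,
                             IntegerVector dims, NumericVector center,
                             double radius) {
  int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  double r2 = radius * radius;
  int i0 = std::max(0, (int)std::ceil(center[0] - radius));
  int i1 = std::min(n1 - 1, (int)std::floor(center[0] + radius));
  int j0 = std::max(0, (int)std::ceil(center[1] - radius));
  int j1 = std::min(n2 - 1, (int)std::floor(center[1] + radius));
  int k0 = std::max(0, (int)std::ceil(center[2] - radius));
  int k1 = std::min(n3 - 1, (int)std::floor(center[2] + radius));
  double nb = 0, nm = 0, nsph = 0;
  for (int k = k0; k <= k1; k++) {
    double dz = k - center[2];
    for (int j = j0; j <= j1; j++) {
      double dy = j - center[1];
      double dyz = dy * dy + dz * dz;
      if (dyz > r2) continue;
      R_xlen_t rowbase = (R_xlen_t)n1 * (j + (R_xlen_t)n2 * k);
      for (int i = i0; i <= i1; i++) {
        double dx = i - center[0];
        if (dx * dx + dyz > r2) continue;
        nsph += 1;
        R_xlen_t idx = rowbase + i;
        if (mask[idx] != 0) {
          nm += 1;
          if (bone[idx] != 0) nb += 1;
        }
      }
    }
  }
  return NumericVector::create(nb, nm, nsph);
}
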