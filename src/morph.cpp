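#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Separable Gaussian blur with kernel renormalisation at the volume faces.
// [[Rcpp::export]]
NumericVector gauss_blur_cpp(NumericVector vol, IntegerVector dims,
                             double sigma) {
  int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  if (sigma <= 0) return clone(vol);
  int h = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> ker(2 * h + 1);
  for (int i = -h; i <= h; i++)
    ker[i + h] = std::exp(-0.5 * i * i / (sigma * sigma));

  std::vector<double> a(vol.begin(), vol.end()), b(n);
  int strides[3] = {1, n1, n1 * n2};
  int sizes[3] = {n1, n2, n3};
  for (int axis = 0; axis < 3; axis++) {
    R_xlen_t stride = strides[axis];
    int len = sizes[axis];
    // iterate over all lines along `axis`
    for (int k = 0; k < (axis == 2 ? 1 : n3); k++) {
      for (int j = 0; j < (axis == 1 ? 1 : n2); j++) {
        for (int i = 0; i < (axis == 0 ? 1 : n1); i++) {
          R_xlen_t base = (R_xlen_t)i + (R_xlen_t)n1 * (j + (R_xlen_t)n2 * k);
          for (int p = 0; p < len; p++) {
            double s = 0, w = 0;
            int lo = std::max(-h, -p), hi = std::min(h, len - 1 - p);
            for (int q = lo; q <= hi; q++) {
              s += ker[q + h] * a[base + stride * (p + q)];
              w += ker[q + h];
            }
            b[base + stride * p] = s / w;
          }
        }
      }
    }
    std::swap(a, b);
  }
  return NumericVector(a.begin(), a.end());
}

// Voxels connected (6-connectivity) to the volume faces through the
// complement of `solid`: the exterior region. Holes inside `solid` are the
// complement voxels not reached.
// [[Rcpp::export]]
LogicalVector flood_exterior_cpp(LogicalVector solid, IntegerVector dims) {
  int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  std::vector<char> ext(n, 0);
  std::queue<R_xlen_t> q;
  auto idx = [&](int i, int j, int k) {
    return (R_xlen_t)i + (R_xlen_t)n1 * (j + (R_xlen_t)n2 * k);
  };
  auto push = [&](int i, int j, int k) {
    R_xlen_t id = idx(i, j, k);
    if (!solid[id] && !ext[id]) {
      ext[id] = 1;
      q.push(id);
    }
  };
  for (int k = 0; k < n3; k++)
    for (int j = 0; j < n2; j++) {
      push(0, j, k);
      push(n1 - 1, j, k);
    }
  for (int k = 0; k < n3; k++)
    for (int i = 0; i < n1; i++) {
      push(i, 0, k);
      push(i, n2 - 1, k);
    }
  for (int j = 0; j < n2; j++)
    for (int i = 0; i < n1; i++) {
      push(i, j, 0);
      push(i, j, n3 - 1);
    }
  const int di[6] = {1, -1, 0, 0, 0, 0};
  const int dj[6] = {0, 0, 1, -1, 0, 0};
  const int dk[6] = {0, 0, 0, 0, 1, -1};
  while (!q.empty()) {
    R_xlen_t id = q.front();
    q.pop();
    int i = (int)(id % n1);
    int j = (int)((id / n1) % n2);
    int k = (int)(id / ((R_xlen_t)n1 * n2));
    for (int m = 0; m < 6; m++) {
      int ii = i + di[m], jj = j + dj[m], kk = k + dk[m];
      if (ii < 0 || ii >= n1 || jj < 0 || jj >= n2 || kk < 0 || kk >= n3)
        continue;
      R_xlen_t id2 = idx(ii, jj, kk);
      if (!solid[id2] && !ext[id2]) {
        ext[id2] = 1;
        q.push(id2);
      }
    }
  }
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; i++) out[i] = ext[i] != 0;
  return out;
}

// Connected-component labelling (26-connectivity when conn26, else 6).
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector fg, IntegerVector dims,
                                   bool conn26) {
  int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  IntegerVector lab(n);  // zero-initialised
  std::queue<R_xlen_t> q;
  int next = 0;
  for (R_xlen_t start = 0; start < n; start++) {
    if (!fg[start] || lab[start] != 0) continue;
    next++;
    lab[start] = next;
    q.push(start);
    while (!q.empty()) {
      R_xlen_t id = q.front();
      q.pop();
      int i = (int)(id % n1);
      int j = (int)((id / n1) % n2);
      int k = (int)(id / ((R_xlen_t)n1 * n2));
      for (int dk = -1; dk <= 1; dk++)
        for (int dj = -1; dj <= 1; dj++)
          for (int di = -1; di <= 1; di++) {
            if (di == 0 && dj == 0 && dk == 0) continue;
            if (!conn26 && (std::abs(di) + std::abs(dj) + std::abs(dk)) != 1)
              continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || ii >= n1 || jj < 0 || jj >= n2 || kk < 0 ||
                kk >= n3)
              continue;
            R_xlen_t id2 =
                (R_xlen_t)ii + (R_xlen_t)n1 * (jj + (R_xlen_t)n2 * kk);
            if (fg[id2] && lab[id2] == 0) {
              lab[id2] = next;
              q.push(id2);
            }
          }
    }
  }
  return lab;
}
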