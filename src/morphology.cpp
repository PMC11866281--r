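#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Voxel index helpers for column-major 3D arrays of dim (d1, d2, d3).
// In this package dim1 = y (rows), dim2 = x (columns), dim3 = z (pages).

static inline R_xlen_t vox(int i, int j, int k, int d1, int d2) {
  return (R_xlen_t)i + (R_xlen_t)d1 * ((R_xlen_t)j + (R_xlen_t)d2 * k);
}

// Connected-component labelling of a logical 3D array.
// connectivity: 6 (faces) or 26 (faces + edges + corners).
// Labels are assigned in scan order starting at 1; 0 is background.
// [[Rcpp::export(name = ".cc_label_3d")]]
IntegerVector cc_label_3d(LogicalVector mask, IntegerVector dims,
                          int connectivity) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  if (mask.size() != n) stop("mask length does not match dims");
  if (connectivity != 6 && connectivity != 26)
    stop("connectivity must be 6 or 26");

  // neighbour offsets
  std::vector<int> di, dj, dk;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        int manh = std::abs(a) + std::abs(b) + std::abs(c);
        if (connectivity == 6 && manh != 1) continue;
        di.push_back(a); dj.push_back(b); dk.push_back(c);
      }
  const int nb = (int)di.size();

  IntegerVector labels(n, 0);
  std::vector<R_xlen_t> queue;
  int current = 0;

  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || labels[s] != 0) continue;
    ++current;
    labels[s] = current;
    queue.clear();
    queue.push_back(s);
    while (!queue.empty()) {
      R_xlen_t v = queue.back(); queue.pop_back();
      int i = (int)(v % d1);
      int j = (int)((v / d1) % d2);
      int k = (int)(v / ((R_xlen_t)d1 * d2));
      for (int m = 0; m < nb; ++m) {
        int ii = i + di[m], jj = j + dj[m], kk = k + dk[m];
        if (ii < 0 || ii >= d1 || jj < 0 || jj >= d2 || kk < 0 || kk >= d3)
          continue;
        R_xlen_t w = vox(ii, jj, kk, d1, d2);
        if (mask[w] && labels[w] == 0) {
          labels[w] = current;
          queue.push_back(w);
        }
      }
    }
  }
  return labels;
}

static std::vector<int> ellipsoid_offsets(NumericVector rvox,
                                          std::vector<int> &di,
                                          std::vector<int> &dj,
                                          std::vector<int> &dk) {
  // rvox = radii in voxels along (dim1, dim2, dim3); zero radius means
  // no extent along that axis.
  int r1 = (int)std::floor(rvox[0] + 1e-9);
  int r2 = (int)std::floor(rvox[1] + 1e-9);
  int r3 = (int)std::floor(rvox[2] + 1e-9);
  double a = rvox[0] > 0 ? rvox[0] : 1e-9;
  double b = rvox[1] > 0 ? rvox[1] : 1e-9;
  double c = rvox[2] > 0 ? rvox[2] : 1e-9;
  for (int i = -r1; i <= r1; ++i)
    for (int j = -r2; j <= r2; ++j)
      for (int k = -r3; k <= r3; ++k) {
        double q = (i / a) * (i / a) + (j / b) * (j / b) + (k / c) * (k / c);
        if (q <= 1.0 + 1e-9) { di.push_back(i); dj.push_back(j); dk.push_back(k); }
      }
  return di;
}

// Binary dilation with an ellipsoidal structuring element (radii in voxels
// along each array dimension). Outside-grid voxels are background.
// [[Rcpp::export(name = ".binary_dilate_3d")]]
LogicalVector binary_dilate_3d(LogicalVector mask, IntegerVector dims,
                               NumericVector rvox) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  if (mask.size() != n) stop("mask length does not match dims");
  std::vector<int> di, dj, dk;
  ellipsoid_offsets(rvox, di, dj, dk);
  const int nb = (int)di.size();
  LogicalVector out(n, 0);
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s]) continue;
    int i = (int)(s % d1);
    int j = (int)((s / d1) % d2);
    int k = (int)(s / ((R_xlen_t)d1 * d2));
    for (int m = 0; m < nb; ++m) {
      int ii = i + di[m], jj = j + dj[m], kk = k + dk[m];
      if (ii < 0 || ii >= d1 || jj < 0 || jj >= d2 || kk < 0 || kk >= d3)
        continue;
      out[vox(ii, jj, kk, d1, d2)] = 1;
    }
  }
  return out;
}

// Binary erosion with the same element. Outside-grid voxels count as
// foreground so that objects truncated by the field of view keep their
// border slices (a slab glued across the full y-range must survive).
// [[Rcpp::export(name = ".binary_erode_3d")]]
LogicalVector binary_erode_3d(LogicalVector mask, IntegerVector dims,
                              NumericVector rvox) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  if (mask.size() != n) stop("mask length does not match dims");
  std::vector<int> di, dj, dk;
  ellipsoid_offsets(rvox, di, dj, dk);
  const int nb = (int)di.size();
  LogicalVector out(n, 0);
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s]) continue;
    int i = (int)(s % d1);
    int j = (int)((s / d1) % d2);
    int k = (int)(s / ((R_xlen_t)d1 * d2));
    bool keep = true;
    for (int m = 0; m < nb && keep; ++m) {
      int ii = i + di[m], jj = j + dj[m], kk = k + dk[m];
      if (ii < 0 || ii >= d1 || jj < 0 || jj >= d2 || kk < 0 || kk >= d3)
        continue; // outside counts as foreground
      if (!mask[vox(ii, jj, kk, d1, d2)]) keep = false;
    }
    out[s] = keep;
  }
  return out;
}

static void conv_axis(std::vector<double> &a, int d1, int d2, int d3,
                      const NumericVector &kern, int axis) {
  const int r = ((int)kern.size() - 1) / 2;
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  std::vector<double> out(n);
  int dim[3] = {d1, d2, d3};
  const int dlen = dim[axis];
  for (R_xlen_t s = 0; s < n; ++s) {
    int idx[3];
    idx[0] = (int)(s % d1);
    idx[1] = (int)((s / d1) % d2);
    idx[2] = (int)(s / ((R_xlen_t)d1 * d2));
    double acc = 0.0;
    for (int m = -r; m <= r; ++m) {
      int p = idx[axis] + m;
      // reflect boundary
      if (p < 0) p = -p - 1;
      if (p >= dlen) p = 2 * dlen - p - 1;
      int jdx[3] = {idx[0], idx[1], idx[2]};
      jdx[axis] = p;
      acc += kern[m + r] * a[vox(jdx[0], jdx[1], jdx[2], d1, d2)];
    }
    out[s] = acc;
  }
  a.swap(out);
}

// Separable 3D convolution with per-axis kernels (odd lengths), reflected
// boundary. Used for Gaussian smoothing of whole z-stacks.
// [[Rcpp::export(name = ".sep_conv_3d")]]
NumericVector sep_conv_3d(NumericVector arr, IntegerVector dims,
                          NumericVector k1, NumericVector k2,
                          NumericVector k3) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  if (arr.size() != n) stop("array length does not match dims");
  if (k1.size() % 2 == 0 || k2.size() % 2 == 0 || k3.size() % 2 == 0)
    stop("kernels must have odd length");
  std::vector<double> a(arr.begin(), arr.end());
  if (k1.size() > 1) conv_axis(a, d1, d2, d3, k1, 0);
  if (k2.size() > 1) conv_axis(a, d1, d2, d3, k2, 1);
  if (k3.size() > 1) conv_axis(a, d1, d2, d3, k3, 2);
  return NumericVector(a.begin(), a.end());
}
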