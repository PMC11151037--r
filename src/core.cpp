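// Compiled kernels for 3D image processing: separable convolution with
// symmetric (reflect) boundary, min/max filters, 6-connected component
// labeling, and per-voxel symmetric 3x3 eigendecomposition for the
// structure gradient tensor.
#include <RcppArmadillo.h>
#include <vector>

using namespace Rcpp;

// Symmetric reflection index (edge voxel duplicated): -1 -> 0, n -> n-1.
static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

// Convolve a 3D array along one axis (1-based: 1 = first/fastest index)
// with an arbitrary odd-length kernel, symmetric boundary.
// [[Rcpp::export(name = ".conv_axis3d")]]
NumericVector conv_axis3d(NumericVector arr, NumericVector kernel, int axis) {
  IntegerVector dims = arr.attr("dim");
  if (dims.size() != 3) stop("expected a 3D array");
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const int klen = kernel.size();
  const int kr = (klen - 1) / 2;
  if (klen % 2 == 0) stop("kernel length must be odd");

  NumericVector out(arr.size());
  out.attr("dim") = dims;
  const double *src = arr.begin();
  double *dst = out.begin();
  const double *kv = kernel.begin();

  // strides for (i, j, k): idx = i + d1*j + d1*d2*k
  const R_xlen_t s1 = 1, s2 = d1, s3 = (R_xlen_t)d1 * d2;
  int n;           // length along the convolved axis
  R_xlen_t sa;     // stride along the convolved axis
  if (axis == 1)      { n = d1; sa = s1; }
  else if (axis == 2) { n = d2; sa = s2; }
  else if (axis == 3) { n = d3; sa = s3; }
  else stop("axis must be 1, 2 or 3");

  // iterate over all lines orthogonal to `axis`
  std::vector<double> line(n);
  int no1, no2; R_xlen_t so1, so2;
  if (axis == 1)      { no1 = d2; so1 = s2; no2 = d3; so2 = s3; }
  else if (axis == 2) { no1 = d1; so1 = s1; no2 = d3; so2 = s3; }
  else                { no1 = d1; so1 = s1; no2 = d2; so2 = s2; }

  for (int b = 0; b < no2; ++b) {
    for (int a = 0; a < no1; ++a) {
      const R_xlen_t base = a * so1 + b * so2;
      for (int i = 0; i < n; ++i) line[i] = src[base + i * sa];
      for (int i = 0; i < n; ++i) {
        double acc = 0.0;
        if (i - kr >= 0 && i + kr < n) {
          for (int t = -kr; t <= kr; ++t) acc += kv[t + kr] * line[i + t];
        } else {
          for (int t = -kr; t <= kr; ++t)
            acc += kv[t + kr] * line[reflect_idx(i + t, n)];
        }
        dst[base + i * sa] = acc;
      }
    }
  }
  return out;
}

// Running min or max filter along one axis, window [-radius, radius],
// symmetric boundary. Used for grayscale/binary erosion and dilation.
// [[Rcpp::export(name = ".minmax_axis3d")]]
NumericVector minmax_axis3d(NumericVector arr, int radius, int axis,
                            bool do_max) {
  IntegerVector dims = arr.attr("dim");
  if (dims.size() != 3) stop("expected a 3D array");
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];

  NumericVector out(arr.size());
  out.attr("dim") = dims;
  const double *src = arr.begin();
  double *dst = out.begin();

  const R_xlen_t s1 = 1, s2 = d1, s3 = (R_xlen_t)d1 * d2;
  int n; R_xlen_t sa;
  if (axis == 1)      { n = d1; sa = s1; }
  else if (axis == 2) { n = d2; sa = s2; }
  else if (axis == 3) { n = d3; sa = s3; }
  else stop("axis must be 1, 2 or 3");

  int no1, no2; R_xlen_t so1, so2;
  if (axis == 1)      { no1 = d2; so1 = s2; no2 = d3; so2 = s3; }
  else if (axis == 2) { no1 = d1; so1 = s1; no2 = d3; so2 = s3; }
  else                { no1 = d1; so1 = s1; no2 = d2; so2 = s2; }

  std::vector<double> line(n);
  for (int b = 0; b < no2; ++b) {
    for (int a = 0; a < no1; ++a) {
      const R_xlen_t base = a * so1 + b * so2;
      for (int i = 0; i < n; ++i) line[i] = src[base + i * sa];
      for (int i = 0; i < n; ++i) {
        double acc = line[reflect_idx(i - radius, n)];
        for (int t = -radius + 1; t <= radius; ++t) {
          double v = line[reflect_idx(i + t, n)];
          if (do_max ? (v > acc) : (v < acc)) acc = v;
        }
        dst[base + i * sa] = acc;
      }
    }
  }
  return out;
}

// 6-connected component labeling of a logical 3D mask (flood fill).
// [[Rcpp::export(name = ".label_components3d")]]
IntegerVector label_components3d(LogicalVector mask) {
  IntegerVector dims = mask.attr("dim");
  if (dims.size() != 3) stop("expected a 3D array");
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const R_xlen_t nvox = (R_xlen_t)d1 * d2 * d3;

  IntegerVector labels(nvox, 0);
  labels.attr("dim") = dims;
  const int *m = mask.begin();
  int *lab = labels.begin();

  std::vector<R_xlen_t> stack;
  int current = 0;
  const R_xlen_t s2 = d1, s3 = (R_xlen_t)d1 * d2;

  for (R_xlen_t start = 0; start < nvox; ++start) {
    if (m[start] != 1 || lab[start] != 0) continue;
    ++current;
    stack.push_back(start);
    lab[start] = current;
    while (!stack.empty()) {
      R_xlen_t v = stack.back(); stack.pop_back();
      const int k = (int)(v / s3);
      const int j = (int)((v - k * s3) / s2);
      const int i = (int)(v - k * s3 - j * s2);
      // 6 face neighbors
      if (i > 0      && m[v - 1]  == 1 && lab[v - 1]  == 0) { lab[v - 1]  = current; stack.push_back(v - 1); }
      if (i < d1 - 1 && m[v + 1]  == 1 && lab[v + 1]  == 0) { lab[v + 1]  = current; stack.push_back(v + 1); }
      if (j > 0      && m[v - s2] == 1 && lab[v - s2] == 0) { lab[v - s2] = current; stack.push_back(v - s2); }
      if (j < d2 - 1 && m[v + s2] == 1 && lab[v + s2] == 0) { lab[v + s2] = current; stack.push_back(v + s2); }
      if (k > 0      && m[v - s3] == 1 && lab[v - s3] == 0) { lab[v - s3] = current; stack.push_back(v - s3); }
      if (k < d3 - 1 && m[v + s3] == 1 && lab[v + s3] == 0) { lab[v + s3] = current; stack.push_back(v + s3); }
    }
  }
  labels.attr("n_components") = current;
  return labels;
}

// Rasterize cylinders (straight fibers) into a coverage array in [0, 1].
// Coverage per voxel is max over fibers of clamp(radius + 0.5 - dist, 0, 1)
// where dist is the exact distance from the voxel center to the fiber axis
// (anti-aliased cylinder distance field). dims are (d1=z, d2=y, d3=x);
// p0 and u are n x 3 matrices of axis points / unit directions in
// (x, y, z) 0-based voxel coordinates.
// [[Rcpp::export(name = ".raster_cylinders")]]
NumericVector raster_cylinders(IntegerVector dims, NumericMatrix p0,
                               NumericMatrix u, NumericVector radius) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const R_xlen_t nvox = (R_xlen_t)d1 * d2 * d3;
  NumericVector cov(nvox, 0.0);
  cov.attr("dim") = dims;
  double *c = cov.begin();
  const R_xlen_t s2 = d1, s3 = (R_xlen_t)d1 * d2;
  const double diag = std::sqrt((double)d1 * d1 + (double)d2 * d2 +
                                (double)d3 * d3);

  for (int f = 0; f < p0.nrow(); ++f) {
    const double px = p0(f, 0), py = p0(f, 1), pz = p0(f, 2);
    const double ux = u(f, 0),  uy = u(f, 1),  uz = u(f, 2);
    const double r = radius[f];
    const int nb = (int)std::ceil(r + 1.0);
    const double step = 0.5;
    for (double t = -diag; t <= diag; t += step) {
      const double cx = px + t * ux, cy = py + t * uy, cz = pz + t * uz;
      if (cx < -r - 1 || cx > d3 + r || cy < -r - 1 || cy > d2 + r ||
          cz < -r - 1 || cz > d1 + r) continue;
      const int x0 = std::max(0, (int)std::floor(cx) - nb);
      const int x1 = std::min(d3 - 1, (int)std::ceil(cx) + nb);
      const int y0 = std::max(0, (int)std::floor(cy) - nb);
      const int y1 = std::min(d2 - 1, (int)std::ceil(cy) + nb);
      const int z0 = std::max(0, (int)std::floor(cz) - nb);
      const int z1 = std::min(d1 - 1, (int)std::ceil(cz) + nb);
      for (int x = x0; x <= x1; ++x) {
        for (int y = y0; y <= y1; ++y) {
          for (int z = z0; z <= z1; ++z) {
            const double wx = x - px, wy = y - py, wz = z - pz;
            const double tt = wx * ux + wy * uy + wz * uz;
            const double dx = wx - tt * ux, dy = wy - tt * uy,
                         dz = wz - tt * uz;
            const double dist = std::sqrt(dx * dx + dy * dy + dz * dz);
            double val = r + 0.5 - dist;
            if (val <= 0) continue;
            if (val > 1) val = 1;
            const R_xlen_t idx = z + y * s2 + x * s3;
            if (val > c[idx]) c[idx] = val;
          }
        }
      }
    }
  }
  return cov;
}

// Per-voxel eigendecomposition of the smoothed structure tensor.
// Inputs are the 6 unique tensor components (x, y, z gradient basis).
// Returns eigenvalues (descending l1 >= l2 >= l3) and the eigenvector of
// the smallest eigenvalue (the locally invariant, i.e. fiber, direction).
// [[Rcpp::export(name = ".tensor_eigen3d")]]
List tensor_eigen3d(NumericVector jxx, NumericVector jyy, NumericVector jzz,
                    NumericVector jxy, NumericVector jxz, NumericVector jyz) {
  const R_xlen_t n = jxx.size();
  NumericVector l1(n), l2(n), l3(n), vx(n), vy(n), vz(n);
  SEXP dim = jxx.attr("dim");

  arma::mat33 A;
  arma::vec3 eigval;
  arma::mat33 eigvec;
  for (R_xlen_t i = 0; i < n; ++i) {
    A(0, 0) = jxx[i]; A(1, 1) = jyy[i]; A(2, 2) = jzz[i];
    A(0, 1) = A(1, 0) = jxy[i];
    A(0, 2) = A(2, 0) = jxz[i];
    A(1, 2) = A(2, 1) = jyz[i];
    arma::eig_sym(eigval, eigvec, A); // ascending
    l1[i] = eigval(2); l2[i] = eigval(1); l3[i] = eigval(0);
    vx[i] = eigvec(0, 0); vy[i] = eigvec(1, 0); vz[i] = eigvec(2, 0);
  }
  l1.attr("dim") = dim; l2.attr("dim") = dim; l3.attr("dim") = dim;
  vx.attr("dim") = dim; vy.attr("dim") = dim; vz.attr("dim") = dim;
  return List::create(_["l1"] = l1, _["l2"] = l2, _["l3"] = l3,
                      _["vx"] = vx, _["vy"] = vy, _["vz"] = vz);
}
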