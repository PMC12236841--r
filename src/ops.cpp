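#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Connected-component labeling on a 3D logical grid (column-major, x fastest).
// connectivity: 6, 18 or 26. A 2D image is the nz == 1 case (26 -> 8-conn,
// 6 -> 4-conn in the plane). Labels are provisional (BFS order); callers
// re-order them deterministically in R.
// [[Rcpp::export]]
IntegerVector cq_label_components(LogicalVector mask, IntegerVector dims,
                                  int connectivity) {
  if (dims.size() != 3) stop("dims must have length 3");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dims");
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");

  // neighbour offsets
  std::vector<int> ox, oy, oz;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        ox.push_back(dx); oy.push_back(dy); oz.push_back(dz);
      }

  IntegerVector labels(n, 0);
  std::vector<R_xlen_t> queue;
  int next_label = 0;

  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || labels[s] != 0) continue;
    ++next_label;
    labels[s] = next_label;
    queue.clear();
    queue.push_back(s);
    while (!queue.empty()) {
      R_xlen_t v = queue.back(); queue.pop_back();
      int x = (int)(v % nx);
      int y = (int)((v / nx) % ny);
      int z = (int)(v / ((R_xlen_t)nx * ny));
      for (size_t k = 0; k < ox.size(); ++k) {
        int xx = x + ox[k], yy = y + oy[k], zz = z + oz[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        R_xlen_t w = (R_xlen_t)xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
        if (mask[w] && labels[w] == 0) {
          labels[w] = next_label;
          queue.push_back(w);
        }
      }
    }
  }
  labels.attr("n_components") = next_label;
  return labels;
}

static inline int reflect_idx(int i, int n) {
  // reflective (mirror, whole-sample) boundary: ... 2 1 0 | 0 1 2 ... n-1 | n-1 n-2 ...
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

static void conv_axis(const std::vector<double> &in, std::vector<double> &out,
                      int nx, int ny, int nz, const NumericVector &k, int axis) {
  const int kn = k.size();
  const int h = (kn - 1) / 2;
  std::vector<double> kv(k.begin(), k.end());
  const int n = (axis == 0) ? nx : (axis == 1) ? ny : nz;
  const R_xlen_t stride = (axis == 0) ? 1
                        : (axis == 1) ? (R_xlen_t)nx
                        : (R_xlen_t)nx * ny;
  std::vector<double> buf(n + 2 * h);
  // iterate over all lines along `axis`: base indices enumerate the other
  // two dimensions
  const int pa = (axis == 0) ? ny : nx;
  const int pb = (axis == 2) ? ny : nz;
  const R_xlen_t sa = (axis == 0) ? (R_xlen_t)nx : 1;
  const R_xlen_t sb = (axis == 2) ? (R_xlen_t)nx : (R_xlen_t)nx * ny;
  for (int b = 0; b < pb; ++b)
    for (int a = 0; a < pa; ++a) {
      const R_xlen_t base = a * sa + b * sb;
      for (int i = 0; i < n; ++i) buf[h + i] = in[base + (R_xlen_t)i * stride];
      for (int i = 0; i < h; ++i) {
        buf[h - 1 - i] = buf[h + reflect_idx(-1 - i, n)];
        buf[h + n + i] = buf[h + reflect_idx(n + i, n)];
      }
      for (int i = 0; i < n; ++i) {
        double acc = 0.0;
        const double *bp = &buf[i];
        for (int j = 0; j < kn; ++j) acc += kv[j] * bp[j];
        out[base + (R_xlen_t)i * stride] = acc;
      }
    }
}

// Separable 3D convolution with reflective boundaries; kernels kx, ky, kz
// must have odd length. Symmetric kernels make convolution == correlation.
// [[Rcpp::export]]
NumericVector cq_convolve_sep(NumericVector img, IntegerVector dims,
                              NumericVector kx, NumericVector ky,
                              NumericVector kz) {
  if (dims.size() != 3) stop("dims must have length 3");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (img.size() != n) stop("image length does not match dims");
  if (kx.size() % 2 == 0 || ky.size() % 2 == 0 || kz.size() % 2 == 0)
    stop("kernels must have odd length");
  std::vector<double> a(img.begin(), img.end()), b(n);
  conv_axis(a, b, nx, ny, nz, kx, 0);
  conv_axis(b, a, nx, ny, nz, ky, 1);
  conv_axis(a, b, nx, ny, nz, kz, 2);
  NumericVector out(n);
  std::copy(b.begin(), b.end(), out.begin());
  out.attr("dim") = dims;
  return out;
}

// Dense (non-separable) 3D convolution, reflective boundaries. kdims odd.
// flip = true convolves with the kernel reflected through its centre
// (i.e. true convolution); flip = false computes correlation.
// [[Rcpp::export]]
NumericVector cq_convolve_full(NumericVector img, IntegerVector dims,
                               NumericVector ker, IntegerVector kdims,
                               bool flip) {
  if (dims.size() != 3 || kdims.size() != 3) stop("dims must have length 3");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int kx = kdims[0], ky = kdims[1], kz = kdims[2];
  if (kx % 2 == 0 || ky % 2 == 0 || kz % 2 == 0)
    stop("kernel extent must be odd along every axis");
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (img.size() != n) stop("image length does not match dims");
  if (ker.size() != (R_xlen_t)kx * ky * kz) stop("kernel length mismatch");
  const int hx = kx / 2, hy = ky / 2, hz = kz / 2;
  NumericVector out(n);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        double acc = 0.0;
        for (int c = 0; c < kz; ++c)
          for (int b = 0; b < ky; ++b)
            for (int a = 0; a < kx; ++a) {
              int ka = flip ? (kx - 1 - a) : a;
              int kb = flip ? (ky - 1 - b) : b;
              int kc = flip ? (kz - 1 - c) : c;
              int xx = reflect_idx(x + a - hx, nx);
              int yy = reflect_idx(y + b - hy, ny);
              int zz = reflect_idx(z + c - hz, nz);
              acc += ker[(R_xlen_t)ka + (R_xlen_t)kx * (kb + (R_xlen_t)ky * kc)] *
                     img[(R_xlen_t)xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz)];
            }
        out[(R_xlen_t)x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)] = acc;
      }
  out.attr("dim") = dims;
  return out;
}

// Rasterize solid ellipsoids into a 3D grid: adds `value` to every voxel whose
// centre lies inside any ellipsoid. Centres cx,cy,cz and semi-axes ax,ay,az in
// voxel units (0-based voxel-centre coordinates).
// [[Rcpp::export]]
NumericVector cq_add_ellipsoids(NumericVector img, IntegerVector dims,
                                NumericVector cx, NumericVector cy,
                                NumericVector cz, NumericVector ax,
                                NumericVector ay, NumericVector az,
                                NumericVector value) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out = clone(img);
  const int np = cx.size();
  for (int p = 0; p < np; ++p) {
    int x0 = std::max(0, (int)std::floor(cx[p] - ax[p]));
    int x1 = std::min(nx - 1, (int)std::ceil(cx[p] + ax[p]));
    int y0 = std::max(0, (int)std::floor(cy[p] - ay[p]));
    int y1 = std::min(ny - 1, (int)std::ceil(cy[p] + ay[p]));
    int z0 = std::max(0, (int)std::floor(cz[p] - az[p]));
    int z1 = std::min(nz - 1, (int)std::ceil(cz[p] + az[p]));
    for (int z = z0; z <= z1; ++z)
      for (int y = y0; y <= y1; ++y)
        for (int x = x0; x <= x1; ++x) {
          double u = (x - cx[p]) / ax[p];
          double v = (y - cy[p]) / ay[p];
          double w = (z - cz[p]) / az[p];
          if (u * u + v * v + w * w <= 1.0)
            out[(R_xlen_t)x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)] += value[p];
        }
  }
  out.attr("dim") = dims;
  return out;
}
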