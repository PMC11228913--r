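#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
using namespace Rcpp;

// Arrays are stored column-major with dims (nz, ny, nx): the z index varies
// fastest, so linear scan order == raster order used for deterministic labels.

static inline R_xlen_t idx3(int z, int y, int x, int nz, int ny) {
  return (R_xlen_t)z + (R_xlen_t)nz * ((R_xlen_t)y + (R_xlen_t)ny * (R_xlen_t)x);
}

// union-find with path halving
static int uf_find(std::vector<int> &parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

static void uf_union(std::vector<int> &parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra < rb) parent[rb] = ra; else if (rb < ra) parent[ra] = rb;
}

// Connectivity-6 (face adjacency) connected-component labeling.
// Returns integer array of the same shape; labels 1..n in raster order of
// each component's first-encountered voxel; attribute "n_objects".
// [[Rcpp::export(name = ".label6_cpp")]]
IntegerVector label6_cpp(LogicalVector mask, IntegerVector dim) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (mask.size() != n) stop("mask length does not match dim");

  // provisional labels: one per foreground voxel, merged by union-find
  std::vector<int> prov(n, -1);
  std::vector<int> parent;
  parent.reserve(1024);

  R_xlen_t i = 0;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z, ++i) {
        if (mask[i] == TRUE) {
          int lab = (int)parent.size();
          parent.push_back(lab);
          prov[i] = lab;
          // merge with already-visited face neighbors (lower z, y, x)
          if (z > 0 && prov[i - 1] >= 0) uf_union(parent, lab, prov[i - 1]);
          if (y > 0) {
            R_xlen_t j = idx3(z, y - 1, x, nz, ny);
            if (prov[j] >= 0) uf_union(parent, lab, prov[j]);
          }
          if (x > 0) {
            R_xlen_t j = idx3(z, y, x - 1, nz, ny);
            if (prov[j] >= 0) uf_union(parent, lab, prov[j]);
          }
        }
      }

  // relabel roots consecutively in raster order of first occurrence
  std::vector<int> final_lab(parent.size(), 0);
  int next = 0;
  IntegerVector out(n, 0);
  for (R_xlen_t k = 0; k < n; ++k) {
    if (prov[k] >= 0) {
      int r = uf_find(parent, prov[k]);
      if (final_lab[r] == 0) final_lab[r] = ++next;
      out[k] = final_lab[r];
    }
  }
  out.attr("dim") = dim;
  out.attr("n_objects") = next;
  return out;
}

// Per-label statistics in one pass. `valid` (optional, same shape) marks the
// analyzed region (e.g. the crop circle); faces toward invalid voxels count
// as exposed and set the border flag, as do faces on the volume boundary
// adjacent to invalid/outside space.
// Returns a list of vectors indexed by label 1..n_labels.
// [[Rcpp::export(name = ".region_stats_cpp")]]
List region_stats_cpp(IntegerVector labels, IntegerVector dim,
                      Nullable<LogicalVector> valid_ = R_NilValue) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (labels.size() != n) stop("labels length does not match dim");
  LogicalVector valid;
  bool has_valid = valid_.isNotNull();
  if (has_valid) {
    valid = valid_.get();
    if (valid.size() != n) stop("valid length does not match dim");
  }

  int nlab = 0;
  for (R_xlen_t k = 0; k < n; ++k) if (labels[k] > nlab) nlab = labels[k];

  std::vector<double> cnt(nlab, 0), sz(nlab, 0), sy(nlab, 0), sx(nlab, 0);
  std::vector<double> faces(nlab, 0);
  std::vector<int> border(nlab, 0);
  std::vector<int> z0(nlab, nz), z1(nlab, -1), y0(nlab, ny), y1(nlab, -1),
                   x0(nlab, nx), x1(nlab, -1);

  const int dz[6] = {-1, 1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, -1, 1, 0, 0};
  const int dx[6] = {0, 0, 0, 0, -1, 1};

  R_xlen_t i = 0;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z, ++i) {
        int lab = labels[i];
        if (lab <= 0) continue;
        int L = lab - 1;
        cnt[L] += 1; sz[L] += z; sy[L] += y; sx[L] += x;
        if (z < z0[L]) z0[L] = z; if (z > z1[L]) z1[L] = z;
        if (y < y0[L]) y0[L] = y; if (y > y1[L]) y1[L] = y;
        if (x < x0[L]) x0[L] = x; if (x > x1[L]) x1[L] = x;
        for (int d = 0; d < 6; ++d) {
          int zz = z + dz[d], yy = y + dy[d], xx = x + dx[d];
          if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) {
            faces[L] += 1; border[L] = 1;
          } else {
            R_xlen_t j = idx3(zz, yy, xx, nz, ny);
            if (labels[j] != lab) faces[L] += 1;
            if (has_valid && valid[j] == FALSE) border[L] = 1;
          }
        }
      }

  return List::create(
    _["voxel_count"] = NumericVector(cnt.begin(), cnt.end()),
    _["sum_z"] = NumericVector(sz.begin(), sz.end()),
    _["sum_y"] = NumericVector(sy.begin(), sy.end()),
    _["sum_x"] = NumericVector(sx.begin(), sx.end()),
    _["exposed_faces"] = NumericVector(faces.begin(), faces.end()),
    _["touches_border"] = IntegerVector(border.begin(), border.end()),
    _["z_min"] = IntegerVector(z0.begin(), z0.end()),
    _["z_max"] = IntegerVector(z1.begin(), z1.end()),
    _["y_min"] = IntegerVector(y0.begin(), y0.end()),
    _["y_max"] = IntegerVector(y1.begin(), y1.end()),
    _["x_min"] = IntegerVector(x0.begin(), x0.end()),
    _["x_max"] = IntegerVector(x1.begin(), x1.end()));
}

static void gauss_kernel(double sd, std::vector<double> &k) {
  int r = (int)std::ceil(4.0 * sd);
  k.assign(2 * r + 1, 0.0);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * (double)i * i / (sd * sd));
    s += k[i + r];
  }
  for (double &v : k) v /= s;
}

// separable 1-D convolution along the given axis (zero padding)
static void conv_axis(std::vector<double> &a, int nz, int ny, int nx,
                      const std::vector<double> &k, int axis) {
  int r = ((int)k.size() - 1) / 2;
  std::vector<double> out(a.size(), 0.0);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        double acc = 0.0;
        for (int o = -r; o <= r; ++o) {
          int zz = z, yy = y, xx = x;
          if (axis == 0) zz += o; else if (axis == 1) yy += o; else xx += o;
          if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
            continue;
          acc += k[o + r] * a[idx3(zz, yy, xx, nz, ny)];
        }
        out[idx3(z, y, x, nz, ny)] = acc;
      }
  a.swap(out);
}

// Coarea surface-area estimate of a binary mask in voxel-face units:
// Gaussian-smooth the indicator, integrate |grad| (central differences).
// Caller must pad the mask so the object does not touch the array boundary.
// [[Rcpp::export(name = ".coarea_surface_cpp")]]
double coarea_surface_cpp(LogicalVector mask, IntegerVector dim, double sd) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (mask.size() != n) stop("mask length does not match dim");
  std::vector<double> a(n);
  for (R_xlen_t i = 0; i < n; ++i) a[i] = mask[i] == TRUE ? 1.0 : 0.0;
  std::vector<double> k;
  gauss_kernel(sd, k);
  conv_axis(a, nz, ny, nx, k, 0);
  conv_axis(a, nz, ny, nx, k, 1);
  conv_axis(a, nz, ny, nx, k, 2);
  double area = 0.0;
  for (int x = 1; x < nx - 1; ++x)
    for (int y = 1; y < ny - 1; ++y)
      for (int z = 1; z < nz - 1; ++z) {
        double gz = 0.5 * (a[idx3(z + 1, y, x, nz, ny)] - a[idx3(z - 1, y, x, nz, ny)]);
        double gy = 0.5 * (a[idx3(z, y + 1, x, nz, ny)] - a[idx3(z, y - 1, x, nz, ny)]);
        double gx = 0.5 * (a[idx3(z, y, x + 1, nz, ny)] - a[idx3(z, y, x - 1, nz, ny)]);
        area += std::sqrt(gz * gz + gy * gy + gx * gx);
      }
  return area;
}

// Grayscale erosion/dilation of a binary mask by a digital ball (radius r
// voxels); op = 0 erode, 1 dilate. Used by the optional morphological opening.
// [[Rcpp::export(name = ".ball_morph_cpp")]]
LogicalVector ball_morph_cpp(LogicalVector mask, IntegerVector dim,
                             double radius, int op) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (mask.size() != n) stop("mask length does not match dim");
  int r = (int)std::floor(radius);
  std::vector<std::array<int, 3> > offs;
  for (int a = -r; a <= r; ++a)
    for (int b = -r; b <= r; ++b)
      for (int c = -r; c <= r; ++c)
        if ((double)(a * a + b * b + c * c) <= radius * radius)
          offs.push_back({{a, b, c}});
  LogicalVector out(n);
  R_xlen_t i = 0;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z, ++i) {
        bool acc = (op == 0);
        for (size_t t = 0; t < offs.size(); ++t) {
          int zz = z + offs[t][0], yy = y + offs[t][1], xx = x + offs[t][2];
          bool v;
          if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
            v = false;  // outside treated as background
          else
            v = mask[idx3(zz, yy, xx, nz, ny)] == TRUE;
          if (op == 0) { if (!v) { acc = false; break; } }
          else { if (v) { acc = true; break; } }
        }
        out[i] = acc;
      }
  out.attr("dim") = dim;
  return out;
}
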