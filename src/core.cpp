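#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// Voxel grids are R arrays with dim = c(nz, ny, nx), column-major, so the
// linear index of (z, y, x) (0-based) is z + nz * (y + ny * x).

static inline int lin(int z, int y, int x, int nz, int ny) {
  return z + nz * (y + ny * x);
}

// Enumerate the 26-neighbourhood (8-neighbourhood when nz == 1).
static void neighbours26(int idx, int nz, int ny, int nx,
                         std::vector<int> &out) {
  out.clear();
  int z = idx % nz;
  int rest = idx / nz;
  int y = rest % ny;
  int x = rest / ny;
  for (int dz = -1; dz <= 1; ++dz) {
    int zz = z + dz;
    if (zz < 0 || zz >= nz) continue;
    for (int dy = -1; dy <= 1; ++dy) {
      int yy = y + dy;
      if (yy < 0 || yy >= ny) continue;
      for (int dx = -1; dx <= 1; ++dx) {
        int xx = x + dx;
        if (xx < 0 || xx >= nx) continue;
        if (dz == 0 && dy == 0 && dx == 0) continue;
        out.push_back(lin(zz, yy, xx, nz, ny));
      }
    }
  }
}

// [[Rcpp::export(name = ".label26_cpp")]]
IntegerVector label26_cpp(LogicalVector mask, IntegerVector dims) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (mask.size() != n) stop("mask length does not match dims");
  IntegerVector labels(n, 0);
  std::vector<int> stack, nb;
  int next = 0;
  for (R_xlen_t start = 0; start < n; ++start) {
    if (!mask[start] || labels[start] != 0) continue;
    ++next;
    labels[start] = next;
    stack.push_back((int)start);
    while (!stack.empty()) {
      int cur = stack.back();
      stack.pop_back();
      neighbours26(cur, nz, ny, nx, nb);
      for (int v : nb) {
        if (mask[v] && labels[v] == 0) {
          labels[v] = next;
          stack.push_back(v);
        }
      }
    }
  }
  labels.attr("n") = next;
  return labels;
}

struct PQItem {
  double intensity;
  long order;
  int idx;
  int label;
};

struct PQCompare {
  bool operator()(const PQItem &a, const PQItem &b) const {
    if (a.intensity != b.intensity) return a.intensity < b.intensity;
    return a.order > b.order;  // FIFO among equal intensities
  }
};

// Seeded watershed by ordered flooding: voxels are claimed in order of
// decreasing intensity starting from the markers, so each masked voxel joins
// the catchment basin of the marker it is connected to by the highest path.
// [[Rcpp::export(name = ".watershed3d_cpp")]]
IntegerVector watershed3d_cpp(NumericVector intensity, LogicalVector mask,
                              IntegerVector markers, IntegerVector dims) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (intensity.size() != n || mask.size() != n || markers.size() != n)
    stop("input lengths do not match dims");
  IntegerVector labels(n, 0);
  std::priority_queue<PQItem, std::vector<PQItem>, PQCompare> pq;
  long order = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (markers[i] > 0 && mask[i]) {
      labels[i] = markers[i];
      pq.push({intensity[i], order++, (int)i, markers[i]});
    }
  }
  std::vector<int> nb;
  while (!pq.empty()) {
    PQItem it = pq.top();
    pq.pop();
    neighbours26(it.idx, nz, ny, nx, nb);
    for (int v : nb) {
      if (mask[v] && labels[v] == 0) {
        labels[v] = it.label;
        pq.push({intensity[v], order++, v, it.label});
      }
    }
  }
  return labels;
}

// Local maxima of `intensity` restricted to `mask` (only masked neighbours
// are compared, so every mask component contains at least one maximum),
// 26-neighbourhood, plateaus included; plateau consolidation happens in R.
// [[Rcpp::export(name = ".local_maxima3d_cpp")]]
LogicalVector local_maxima3d_cpp(NumericVector intensity, LogicalVector mask,
                                 IntegerVector dims) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  LogicalVector out(n, false);
  std::vector<int> nb;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i]) continue;
    neighbours26((int)i, nz, ny, nx, nb);
    bool is_max = true;
    for (int v : nb) {
      if (mask[v] && intensity[v] > intensity[i]) { is_max = false; break; }
    }
    out[i] = is_max;
  }
  return out;
}

// One separable Gaussian pass along the given axis (0 = z, 1 = y, 2 = x)
// with a truncated kernel renormalised at the borders.
static void blur_axis(std::vector<double> &src, std::vector<double> &dst,
                      int nz, int ny, int nx, int axis, double sigma) {
  int len = (axis == 0) ? nz : (axis == 1) ? ny : nx;
  if (sigma <= 0 || len == 1) { dst = src; return; }
  int radius = (int)std::ceil(3.0 * sigma);
  std::vector<double> kern(2 * radius + 1);
  for (int k = -radius; k <= radius; ++k)
    kern[k + radius] = std::exp(-0.5 * (double)k * k / (sigma * sigma));
  int stride = (axis == 0) ? 1 : (axis == 1) ? nz : nz * ny;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int pos = (axis == 0) ? z : (axis == 1) ? y : x;
        int base = lin(z, y, x, nz, ny);
        double acc = 0.0, wsum = 0.0;
        int lo = std::max(-radius, -pos), hi = std::min(radius, len - 1 - pos);
        for (int k = lo; k <= hi; ++k) {
          double w = kern[k + radius];
          acc += w * src[base + k * stride];
          wsum += w;
        }
        dst[base] = acc / wsum;
      }
}

// [[Rcpp::export(name = ".gauss_blur3d_cpp")]]
NumericVector gauss_blur3d_cpp(NumericVector input, IntegerVector dims,
                               NumericVector sigma) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (input.size() != n) stop("input length does not match dims");
  std::vector<double> a(input.begin(), input.end()), b(n);
  blur_axis(a, b, nz, ny, nx, 0, sigma[0]);
  blur_axis(b, a, nz, ny, nx, 1, sigma[1]);
  blur_axis(a, b, nz, ny, nx, 2, sigma[2]);
  return NumericVector(b.begin(), b.end());
}
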