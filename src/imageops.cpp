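// Low-level raster primitives backing nucleus segmentation and foci
// detection: separable convolution, grayscale morphology, connected
// components, exact Euclidean distance transform, marker-directed
// watershed, Canny hysteresis and local-maximum seeding.
//
// All matrices are R column-major with (row, col) = (y, x), 0-based here.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>
#include <algorithm>

using namespace Rcpp;

static inline int reflect(int i, int n) {
  // reflect-101 boundary: n = 5 -> ..., 2, 1, 0, 1, 2, 3, 4, 3, 2, ...
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i;
    if (i >= n) i = 2 * (n - 1) - i;
  }
  return i;
}

// [[Rcpp::export]]
NumericMatrix cpp_convolve_sep(const NumericMatrix& img, const NumericVector& kernel) {
  const int nr = img.nrow(), nc = img.ncol(), k = kernel.size();
  const int half = k / 2;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  // along rows (y direction)
  for (int x = 0; x < nc; ++x)
    for (int y = 0; y < nr; ++y) {
      double acc = 0.0;
      for (int j = 0; j < k; ++j) acc += kernel[j] * img(reflect(y + j - half, nr), x);
      tmp(y, x) = acc;
    }
  // along columns (x direction)
  for (int x = 0; x < nc; ++x)
    for (int y = 0; y < nr; ++y) {
      double acc = 0.0;
      for (int j = 0; j < k; ++j) acc += kernel[j] * tmp(y, reflect(x + j - half, nc));
      out(y, x) = acc;
    }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_gray_morph(const NumericMatrix& img, const IntegerVector& dy,
                             const IntegerVector& dx, bool dilate) {
  const int nr = img.nrow(), nc = img.ncol(), m = dy.size();
  NumericMatrix out(nr, nc);
  for (int x = 0; x < nc; ++x)
    for (int y = 0; y < nr; ++y) {
      double best = dilate ? -std::numeric_limits<double>::infinity()
                           :  std::numeric_limits<double>::infinity();
      for (int j = 0; j < m; ++j) {
        int yy = y + dy[j], xx = x + dx[j];
        if (yy < 0 || yy >= nr || xx < 0 || xx >= nc) continue; // SE clipped at border
        double v = img(yy, xx);
        if (dilate ? (v > best) : (v < best)) best = v;
      }
      out(y, x) = best;
    }
  return out;
}

// [[Rcpp::export]]
IntegerMatrix cpp_label(const LogicalMatrix& mask, int connectivity = 8) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  const int dy8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dx8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dy4[4] = {-1, 0, 0, 1};
  const int dx4[4] = {0, -1, 1, 0};
  const int* dy = (connectivity == 8) ? dy8 : dy4;
  const int* dx = (connectivity == 8) ? dx8 : dx4;
  const int nn = (connectivity == 8) ? 8 : 4;
  int next = 0;
  std::vector<std::pair<int,int> > stack;
  for (int x0 = 0; x0 < nc; ++x0)
    for (int y0 = 0; y0 < nr; ++y0) {
      if (!mask(y0, x0) || lab(y0, x0) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(std::make_pair(y0, x0));
      lab(y0, x0) = next;
      while (!stack.empty()) {
        std::pair<int,int> p = stack.back();
        stack.pop_back();
        for (int j = 0; j < nn; ++j) {
          int yy = p.first + dy[j], xx = p.second + dx[j];
          if (yy < 0 || yy >= nr || xx < 0 || xx >= nc) continue;
          if (mask(yy, xx) && lab(yy, xx) == 0) {
            lab(yy, xx) = next;
            stack.push_back(std::make_pair(yy, xx));
          }
        }
      }
    }
  return lab;
}

// Felzenszwalb-Huttenlocher 1D squared distance transform (lower envelope)
static void edt1d(const std::vector<double>& f, std::vector<double>& d) {
  const int n = (int)f.size();
  d.assign(n, 0.0);
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) / (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) / (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_edt(const LogicalMatrix& mask) {
  // Euclidean distance of each foreground pixel to the nearest background pixel
  const int nr = mask.nrow(), nc = mask.ncol();
  const double INF = 1e20;
  NumericMatrix g(nr, nc);
  std::vector<double> f(std::max(nr, nc)), d;
  for (int x = 0; x < nc; ++x) {
    for (int y = 0; y < nr; ++y) f[y] = mask(y, x) ? INF : 0.0;
    std::vector<double> col(f.begin(), f.begin() + nr);
    edt1d(col, d);
    for (int y = 0; y < nr; ++y) g(y, x) = d[y];
  }
  NumericMatrix out(nr, nc);
  for (int y = 0; y < nr; ++y) {
    for (int x = 0; x < nc; ++x) f[x] = g(y, x);
    std::vector<double> row(f.begin(), f.begin() + nc);
    edt1d(row, d);
    for (int x = 0; x < nc; ++x) out(y, x) = std::sqrt(d[x]);
  }
  return out;
}

struct WsPix {
  double h;
  long order;
  int y, x;
};
struct WsCmp {
  bool operator()(const WsPix& a, const WsPix& b) const {
    if (a.h != b.h) return a.h > b.h;   // lowest height first
    return a.order > b.order;           // FIFO tie-break -> deterministic
  }
};

// [[Rcpp::export]]
IntegerMatrix cpp_watershed(const NumericMatrix& height, const IntegerMatrix& markers,
                            const LogicalMatrix& mask) {
  // Priority-flood from labelled markers, restricted to mask; unflooded
  // mask pixels (disconnected from any marker) stay 0.
  const int nr = height.nrow(), nc = height.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  std::priority_queue<WsPix, std::vector<WsPix>, WsCmp> pq;
  long order = 0;
  const int dy[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dx[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  for (int x = 0; x < nc; ++x)
    for (int y = 0; y < nr; ++y)
      if (markers(y, x) > 0 && mask(y, x)) {
        lab(y, x) = markers(y, x);
        WsPix p = {height(y, x), order++, y, x};
        pq.push(p);
      }
  while (!pq.empty()) {
    WsPix p = pq.top();
    pq.pop();
    for (int j = 0; j < 8; ++j) {
      int yy = p.y + dy[j], xx = p.x + dx[j];
      if (yy < 0 || yy >= nr || xx < 0 || xx >= nc) continue;
      if (!mask(yy, xx) || lab(yy, xx) != 0) continue;
      lab(yy, xx) = lab(p.y, p.x);
      WsPix q = {height(yy, xx), order++, yy, xx};
      pq.push(q);
    }
  }
  return lab;
}

// [[Rcpp::export]]
LogicalMatrix cpp_hysteresis(const LogicalMatrix& strong, const LogicalMatrix& weak) {
  // keep weak pixels 8-connected to a strong pixel
  const int nr = strong.nrow(), nc = strong.ncol();
  LogicalMatrix out(nr, nc);
  std::fill(out.begin(), out.end(), false);
  std::vector<std::pair<int,int> > stack;
  const int dy[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dx[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  for (int x = 0; x < nc; ++x)
    for (int y = 0; y < nr; ++y)
      if (strong(y, x) && !out(y, x)) {
        out(y, x) = true;
        stack.push_back(std::make_pair(y, x));
        while (!stack.empty()) {
          std::pair<int,int> p = stack.back();
          stack.pop_back();
          for (int j = 0; j < 8; ++j) {
            int yy = p.first + dy[j], xx = p.second + dx[j];
            if (yy < 0 || yy >= nr || xx < 0 || xx >= nc) continue;
            if (weak(yy, xx) && !out(yy, xx)) {
              out(yy, xx) = true;
              stack.push_back(std::make_pair(yy, xx));
            }
          }
        }
      }
  return out;
}

// [[Rcpp::export]]
DataFrame cpp_local_maxima(const NumericMatrix& img, const LogicalMatrix& mask,
                           int min_distance, double threshold) {
  // candidate = pixel inside mask, >= threshold, maximal within its
  // (2r+1)^2 neighbourhood; then greedy min-distance suppression in
  // decreasing intensity order (plateaus keep the first pixel scanned).
  const int nr = img.nrow(), nc = img.ncol();
  const int r = std::max(1, min_distance);
  std::vector<int> ys, xs;
  std::vector<double> vs;
  for (int x = 0; x < nc; ++x)
    for (int y = 0; y < nr; ++y) {
      if (!mask(y, x)) continue;
      double v = img(y, x);
      if (v < threshold) continue;
      bool ismax = true;
      for (int ddy = -r; ddy <= r && ismax; ++ddy)
        for (int ddx = -r; ddx <= r; ++ddx) {
          if (ddy == 0 && ddx == 0) continue;
          int yy = y + ddy, xx = x + ddx;
          if (yy < 0 || yy >= nr || xx < 0 || xx >= nc) continue;
          double w = img(yy, xx);
          if (w > v || (w == v && (xx < x || (xx == x && yy < y)))) { ismax = false; break; }
        }
      if (ismax) { ys.push_back(y); xs.push_back(x); vs.push_back(v); }
    }
  // order by intensity desc, stable
  std::vector<int> idx(ys.size());
  for (size_t i = 0; i < idx.size(); ++i) idx[i] = (int)i;
  std::stable_sort(idx.begin(), idx.end(),
                   [&](int a, int b) { return vs[a] > vs[b]; });
  std::vector<int> keep;
  const double mind2 = (double)min_distance * min_distance;
  for (size_t ii = 0; ii < idx.size(); ++ii) {
    int i = idx[ii];
    bool ok = true;
    for (size_t jj = 0; jj < keep.size(); ++jj) {
      int j = keep[jj];
      double dyv = ys[i] - ys[j], dxv = xs[i] - xs[j];
      if (dyv * dyv + dxv * dxv < mind2) { ok = false; break; }
    }
    if (ok) keep.push_back(i);
  }
  IntegerVector oy(keep.size()), ox(keep.size());
  NumericVector ov(keep.size());
  for (size_t i = 0; i < keep.size(); ++i) {
    oy[i] = ys[keep[i]];
    ox[i] = xs[keep[i]];
    ov[i] = vs[keep[i]];
  }
  return DataFrame::create(_["y"] = oy, _["x"] = ox, _["value"] = ov);
}
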