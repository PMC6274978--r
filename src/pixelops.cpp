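#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <queue>
#include <vector>
using namespace Rcpp;

// Window span around index i (0-based) for a side-w window: lo = (w-1)/2
// pixels before, hi = w/2 pixels after.  Symmetric for odd w; for even w the
// extra pixel goes after the centre.  Windows are cropped at image borders:
// statistics are taken over the valid intersection only.
static inline void win_span(int i, int n, int w, int &a, int &b) {
  int lo = (w - 1) / 2, hi = w / 2;
  a = std::max(0, i - lo);
  b = std::min(n - 1, i + hi);
}

// [[Rcpp::export]]
NumericMatrix median_filter_cpp(NumericMatrix img, int w) {
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  std::vector<double> buf;
  buf.reserve((size_t)w * w);
  for (int j = 0; j < nc; ++j) {
    int ca, cb;
    win_span(j, nc, w, ca, cb);
    for (int i = 0; i < nr; ++i) {
      int ra, rb;
      win_span(i, nr, w, ra, rb);
      buf.clear();
      for (int jj = ca; jj <= cb; ++jj)
        for (int ii = ra; ii <= rb; ++ii)
          buf.push_back(img(ii, jj));
      size_t n = buf.size(), mid = n / 2;
      std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
      double m = buf[mid];
      if (n % 2 == 0) {
        // even count: mean of the two central order statistics
        double lo = *std::max_element(buf.begin(), buf.begin() + mid);
        m = (m + lo) / 2.0;
      }
      out(i, j) = m;
    }
  }
  return out;
}

// Niblack local threshold T = m + k*s via summed-area tables of I and I^2.
// s is the population standard deviation sqrt(E[I^2] - E[I]^2), clamped at 0
// against round-off.  Foreground iff I > T (strict).
// [[Rcpp::export]]
LogicalMatrix niblack_threshold_cpp(NumericMatrix img, int w, double k) {
  int nr = img.nrow(), nc = img.ncol();
  // integral images with a zero top row / left column
  std::vector<double> S((size_t)(nr + 1) * (nc + 1), 0.0);
  std::vector<double> S2((size_t)(nr + 1) * (nc + 1), 0.0);
  size_t stride = nr + 1;
  for (int j = 1; j <= nc; ++j) {
    for (int i = 1; i <= nr; ++i) {
      double v = img(i - 1, j - 1);
      size_t id = (size_t)j * stride + i;
      S[id]  = v     + S[id - stride] + S[id - 1] - S[id - stride - 1];
      S2[id] = v * v + S2[id - stride] + S2[id - 1] - S2[id - stride - 1];
    }
  }
  LogicalMatrix out(nr, nc);
  // guard against summed-area cancellation round-off (windows of constant
  // intensity can yield means off by ~1e-12, flipping the strict compare)
  double scale = 0.0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      scale = std::max(scale, std::fabs(img(i, j)));
  double eps = 1e-9 * (scale + 1.0);
  for (int j = 0; j < nc; ++j) {
    int ca, cb;
    win_span(j, nc, w, ca, cb);
    for (int i = 0; i < nr; ++i) {
      int ra, rb;
      win_span(i, nr, w, ra, rb);
      double n = (double)(rb - ra + 1) * (cb - ca + 1);
      size_t r0 = (size_t)ra, r1 = (size_t)rb + 1;
      size_t c0 = (size_t)ca, c1 = (size_t)cb + 1;
      double sum  = S[c1 * stride + r1] - S[c0 * stride + r1] -
                    S[c1 * stride + r0] + S[c0 * stride + r0];
      double sum2 = S2[c1 * stride + r1] - S2[c0 * stride + r1] -
                    S2[c1 * stride + r0] + S2[c0 * stride + r0];
      double m = sum / n;
      double var = sum2 / n - m * m;
      if (var < 0) var = 0;
      double thr = m + k * std::sqrt(var);
      out(i, j) = img(i, j) > thr + eps;
    }
  }
  return out;
}

// 8-connected component labelling; labels 1..L assigned in raster-scan
// (column-major, as stored; first-pixel) order of discovery.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::queue<std::pair<int, int> > q;
  // raster order: row-major over (row, col) so "first pixel" reads naturally
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      q.push(std::make_pair(i, j));
      while (!q.empty()) {
        std::pair<int, int> p = q.front();
        q.pop();
        for (int di = -1; di <= 1; ++di) {
          for (int dj = -1; dj <= 1; ++dj) {
            if (di == 0 && dj == 0) continue;
            int ii = p.first + di, jj = p.second + dj;
            if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
            if (mask(ii, jj) && lab(ii, jj) == 0) {
              lab(ii, jj) = next;
              q.push(std::make_pair(ii, jj));
            }
          }
        }
      }
    }
  }
  return lab;
}
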