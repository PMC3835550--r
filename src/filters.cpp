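#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <deque>
using namespace Rcpp;

// Edge-inclusive mirror reflection ("symmetric" padding): indices reflect
// with period 2n, so -1 -> 0, n -> n-1, etc. 0-based.
static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  int p = 2 * n;
  i %= p;
  if (i < 0) i += p;
  return (i < n) ? i : p - 1 - i;
}

// Square m x m median filter with symmetric padding. The window spans
// offsets [-floor(m/2), m - floor(m/2) - 1] in each axis; for an even
// number of values the median is the mean of the two middle order
// statistics (as MATLAB's median does).
// [[Rcpp::export]]
NumericMatrix median_filter_cpp(NumericMatrix x, int m) {
  const int n = x.nrow(), r = x.ncol();
  const int lo = -(m / 2), hi = lo + m - 1;
  const int w = m * m;
  NumericMatrix out(n, r);
  // Precompute reflected indices per output position and offset.
  std::vector<int> rref(static_cast<size_t>(n) * m), cref(static_cast<size_t>(r) * m);
  for (int i = 0; i < n; ++i)
    for (int o = 0; o < m; ++o)
      rref[static_cast<size_t>(i) * m + o] = reflect_idx(i + lo + o, n);
  for (int j = 0; j < r; ++j)
    for (int o = 0; o < m; ++o)
      cref[static_cast<size_t>(j) * m + o] = reflect_idx(j + lo + o, r);
  std::vector<double> buf(w);
  const bool even = (w % 2 == 0);
  const int k2 = w / 2, k1 = k2 - 1;  // middle order statistics (0-based)
  for (int j = 0; j < r; ++j) {
    const int* cr = &cref[static_cast<size_t>(j) * m];
    for (int i = 0; i < n; ++i) {
      const int* rr = &rref[static_cast<size_t>(i) * m];
      int t = 0;
      for (int oc = 0; oc < m; ++oc) {
        const double* col = &x(0, cr[oc]);
        for (int orow = 0; orow < m; ++orow) buf[t++] = col[rr[orow]];
      }
      if (even) {
        std::nth_element(buf.begin(), buf.begin() + k1, buf.end());
        double a = buf[k1];
        double b = *std::min_element(buf.begin() + k2, buf.end());
        out(i, j) = (a + b) / 2.0;
      } else {
        std::nth_element(buf.begin(), buf.begin() + k2, buf.end());
        out(i, j) = buf[k2];
      }
    }
  }
  return out;
}

// Connected-component labelling of a logical mask by breadth-first search.
// Scanning is row-major so labels 1,2,... are ordered by each component's
// first pixel in row-major order. connectivity is 4 or 8.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask, int connectivity) {
  const int n = mask.nrow(), r = mask.ncol();
  IntegerMatrix lab(n, r);
  const int dr4[] = {-1, 1, 0, 0}, dc4[] = {0, 0, -1, 1};
  const int dr8[] = {-1, 1, 0, 0, -1, -1, 1, 1}, dc8[] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int* dr = (connectivity == 8) ? dr8 : dr4;
  const int* dc = (connectivity == 8) ? dc8 : dc4;
  const int nd = (connectivity == 8) ? 8 : 4;
  int next = 0;
  std::deque<std::pair<int, int> > queue;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < r; ++j) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      queue.push_back(std::make_pair(i, j));
      while (!queue.empty()) {
        std::pair<int, int> q = queue.front();
        queue.pop_front();
        for (int d = 0; d < nd; ++d) {
          int ni = q.first + dr[d], nj = q.second + dc[d];
          if (ni < 0 || ni >= n || nj < 0 || nj >= r) continue;
          if (mask(ni, nj) && lab(ni, nj) == 0) {
            lab(ni, nj) = next;
            queue.push_back(std::make_pair(ni, nj));
          }
        }
      }
    }
  }
  return lab;
}
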