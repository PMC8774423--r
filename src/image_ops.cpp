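#include <Rcpp.h>
#include <queue>
#include <vector>
#include <limits>
#include <cmath>

using namespace Rcpp;

// Exact Euclidean distance transform (Felzenszwalb & Huttenlocher lower
// envelope of parabolas), applied along columns then rows. Input: binary
// matrix, foreground != 0. Output: distance (pixels) to the nearest
// background pixel; 0 on background.

static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (q - v[k]) * (double)(q - v[k]) + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_edt(IntegerMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  const double INF = 1e20;
  NumericMatrix out(nr, nc);
  // column pass
  std::vector<double> f(std::max(nr, nc)), d(std::max(nr, nc));
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) f[r] = mask(r, c) != 0 ? INF : 0.0;
    dt1d(f, d, nr);
    for (int r = 0; r < nr; ++r) out(r, c) = d[r];
  }
  // row pass
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) f[c] = out(r, c);
    dt1d(f, d, nc);
    for (int c = 0; c < nc; ++c) out(r, c) = std::sqrt(d[c]);
  }
  return out;
}

// Priority-flood watershed. Floods from labelled marker pixels in order of
// increasing altitude, restricted to mask != 0, 8-connectivity. Ties are
// broken by insertion order so the result is deterministic. Every masked
// pixel reachable from a marker receives exactly one label; no watershed
// lines are kept (region semantics).

struct QNode {
  double alt;
  long order;
  int idx;
};
struct QCmp {
  bool operator()(const QNode& a, const QNode& b) const {
    if (a.alt != b.alt) return a.alt > b.alt;  // min-heap on altitude
    return a.order > b.order;                  // FIFO on ties
  }
};

// [[Rcpp::export]]
IntegerMatrix cpp_watershed(NumericMatrix altitude, IntegerMatrix markers,
                            IntegerMatrix mask) {
  int nr = altitude.nrow(), nc = altitude.ncol();
  IntegerMatrix lab(nr, nc);
  std::priority_queue<QNode, std::vector<QNode>, QCmp> pq;
  long order = 0;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      lab(r, c) = markers(r, c);
      if (markers(r, c) > 0 && mask(r, c) != 0)
        pq.push({altitude(r, c), order++, r + c * nr});
    }
  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  while (!pq.empty()) {
    QNode nd = pq.top();
    pq.pop();
    int r = nd.idx % nr, c = nd.idx / nr;
    int l = lab(r, c);
    for (int k = 0; k < 8; ++k) {
      int rr = r + dr[k], cc = c + dc[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      if (mask(rr, cc) == 0 || lab(rr, cc) != 0) continue;
      lab(rr, cc) = l;
      pq.push({altitude(rr, cc), order++, rr + cc * nr});
    }
  }
  return lab;
}

// Connected-component labelling (BFS), labels assigned in raster-scan
// discovery order (column-major, matching R's storage); connectivity 4 or 8.

// [[Rcpp::export]]
IntegerMatrix cpp_label(IntegerMatrix mask, int connectivity) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[4] = {-1, 0, 0, 1};
  const int dc4[4] = {0, -1, 1, 0};
  const int* dr = connectivity == 4 ? dr4 : dr8;
  const int* dc = connectivity == 4 ? dc4 : dc8;
  int nn = connectivity == 4 ? 4 : 8;
  int next = 0;
  std::vector<int> stack;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      if (mask(r, c) == 0 || lab(r, c) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(r + c * nr);
      lab(r, c) = next;
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int r0 = idx % nr, c0 = idx / nr;
        for (int k = 0; k < nn; ++k) {
          int rr = r0 + dr[k], cc = c0 + dc[k];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (mask(rr, cc) == 0 || lab(rr, cc) != 0) continue;
          lab(rr, cc) = next;
          stack.push_back(rr + cc * nr);
        }
      }
    }
  return lab;
}

// Binary dilation (erode = false) or erosion (erode = true) with an
// arbitrary structuring element given as offset vectors. Pixels outside the
// image count as background.

// [[Rcpp::export]]
IntegerMatrix cpp_morph(IntegerMatrix mask, IntegerVector off_r,
                        IntegerVector off_c, bool erode) {
  int nr = mask.nrow(), nc = mask.ncol(), m = off_r.size();
  IntegerMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      if (erode) {
        int keep = 1;
        for (int k = 0; k < m && keep; ++k) {
          int rr = r + off_r[k], cc = c + off_c[k];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc || mask(rr, cc) == 0)
            keep = 0;
        }
        out(r, c) = keep;
      } else {
        int hit = 0;
        for (int k = 0; k < m && !hit; ++k) {
          int rr = r + off_r[k], cc = c + off_c[k];
          if (rr >= 0 && rr < nr && cc >= 0 && cc < nc && mask(rr, cc) != 0)
            hit = 1;
        }
        out(r, c) = hit;
      }
    }
  return out;
}
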