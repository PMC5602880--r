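#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Exact Euclidean distance transform (Felzenszwalb & Huttenlocher lower
// envelope of parabolas, applied per column then per row). Distance of each
// foreground pixel to the nearest zero pixel; zero pixels map to 0.
// ---------------------------------------------------------------------------

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
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export(name = ".cpp_edt")]]
NumericMatrix cpp_edt(IntegerMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  const double INF = 1e18;
  NumericMatrix sq(nr, nc);
  // initialize: 0 on background, INF on foreground
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      sq(i, j) = (mask(i, j) != 0) ? INF : 0.0;
  std::vector<double> f(std::max(nr, nc)), d(std::max(nr, nc));
  // columns
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) f[i] = sq(i, j);
    dt1d(f, d, nr);
    for (int i = 0; i < nr; ++i) sq(i, j) = d[i];
  }
  // rows
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) f[j] = sq(i, j);
    dt1d(f, d, nc);
    for (int j = 0; j < nc; ++j) sq(i, j) = d[j];
  }
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      out(i, j) = std::sqrt(sq(i, j));
  return out;
}

// ---------------------------------------------------------------------------
// Connected-component labelling (4- or 8-connectivity), labels 1..k in
// raster-scan discovery order.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_label")]]
IntegerMatrix cpp_label(IntegerMatrix mask, int connectivity) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  int ndir = (connectivity == 8) ? 8 : 4;
  const int dr[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  std::vector<int> stack;
  int next = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (mask(i, j) == 0 || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      stack.clear();
      stack.push_back(i + j * nr);
      while (!stack.empty()) {
        int p = stack.back();
        stack.pop_back();
        int pi = p % nr, pj = p / nr;
        for (int t = 0; t < ndir; ++t) {
          int qi = pi + dr[t], qj = pj + dc[t];
          if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
          if (mask(qi, qj) != 0 && lab(qi, qj) == 0) {
            lab(qi, qj) = next;
            stack.push_back(qi + qj * nr);
          }
        }
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Seeded watershed by priority flooding of the negated distance map: pixels
// are claimed in order of decreasing D starting from the seeds, restricted to
// the foreground mask. Equivalent to the watershed of -D with seed pixels
// forced to -Inf. Deterministic: FIFO order breaks ties.
// ---------------------------------------------------------------------------

struct WsNode {
  double d;      // distance value (higher = flooded earlier)
  long order;    // insertion order for deterministic ties
  int pix;
  bool operator<(const WsNode& o) const {
    if (d != o.d) return d < o.d;      // max-heap on d
    return order > o.order;            // FIFO among equal d
  }
};

// [[Rcpp::export(name = ".cpp_watershed")]]
IntegerMatrix cpp_watershed(NumericMatrix D, IntegerMatrix mask,
                            IntegerMatrix seed_rc, IntegerVector seed_lab) {
  int nr = D.nrow(), nc = D.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  std::priority_queue<WsNode> pq;
  long order = 0;
  const int dr[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  for (int s = 0; s < seed_rc.nrow(); ++s) {
    int i = seed_rc(s, 0), j = seed_rc(s, 1);
    if (i < 0 || i >= nr || j < 0 || j >= nc)
      stop("seed outside image");
    if (mask(i, j) == 0) stop("seed on background");
    lab(i, j) = seed_lab[s];
    pq.push({std::numeric_limits<double>::infinity(), order++, i + j * nr});
  }
  while (!pq.empty()) {
    WsNode nd = pq.top();
    pq.pop();
    int pi = nd.pix % nr, pj = nd.pix / nr;
    int l = lab(pi, pj);
    for (int t = 0; t < 8; ++t) {
      int qi = pi + dr[t], qj = pj + dc[t];
      if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
      if (mask(qi, qj) == 0 || lab(qi, qj) != 0) continue;
      lab(qi, qj) = l;
      pq.push({D(qi, qj), order++, qi + qj * nr});
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Separable Gaussian blur with reflected borders.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_gauss_blur")]]
NumericMatrix cpp_gauss_blur(NumericMatrix img, double sigma) {
  int nr = img.nrow(), nc = img.ncol();
  if (sigma <= 0) return clone(img);
  int rad = (int)std::ceil(3.0 * sigma);
  std::vector<double> k(2 * rad + 1);
  double s = 0;
  for (int t = -rad; t <= rad; ++t) {
    k[t + rad] = std::exp(-0.5 * t * t / (sigma * sigma));
    s += k[t + rad];
  }
  for (auto& v : k) v /= s;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  // along rows (vertical)
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double acc = 0;
      for (int t = -rad; t <= rad; ++t) {
        int ii = i + t;
        if (ii < 0) ii = -ii - 1;
        if (ii >= nr) ii = 2 * nr - ii - 1;
        acc += k[t + rad] * img(ii, j);
      }
      tmp(i, j) = acc;
    }
  }
  // along columns (horizontal)
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      double acc = 0;
      for (int t = -rad; t <= rad; ++t) {
        int jj = j + t;
        if (jj < 0) jj = -jj - 1;
        if (jj >= nc) jj = 2 * nc - jj - 1;
        acc += k[t + rad] * tmp(i, jj);
      }
      out(i, j) = acc;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Moore-neighbour contour tracing with Jacob's stopping criterion.
// Returns the ordered closed boundary of the (single) 8-connected component
// containing the foreground of `mask`, as 0-based (row, col), starting from
// the topmost-leftmost boundary pixel, counter-clockwise in (x = col,
// y = -row) coordinates.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_trace_contour")]]
IntegerMatrix cpp_trace_contour(IntegerMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  // topmost (smallest row), then leftmost start pixel
  int si = -1, sj = -1;
  for (int i = 0; i < nr && si < 0; ++i)
    for (int j = 0; j < nc; ++j)
      if (mask(i, j) != 0) { si = i; sj = j; break; }
  if (si < 0) return IntegerMatrix(0, 2);
  // Moore neighbourhood in clockwise order starting from W
  const int mr[8] = {0, -1, -1, -1, 0, 1, 1, 1};
  const int mc[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
  auto fg = [&](int i, int j) {
    return i >= 0 && i < nr && j >= 0 && j < nc && mask(i, j) != 0;
  };
  std::vector<int> ri, ci;
  ri.push_back(si); ci.push_back(sj);
  int ci0 = si, cj0 = sj;
  int back = 0;  // index of the backtrack neighbour (entered from the W)
  int cur_i = si, cur_j = sj;
  int first_dir = -1;
  long guard = 0, guard_max = 4L * nr * nc + 16;
  while (true) {
    int found = -1;
    for (int t = 1; t <= 8; ++t) {
      int d = (back + t) % 8;
      int qi = cur_i + mr[d], qj = cur_j + mc[d];
      if (fg(qi, qj)) { found = d; break; }
    }
    if (found < 0) break;  // isolated pixel
    // Jacob's stopping criterion: back at the start pixel and about to
    // repeat the initial move
    if (first_dir >= 0 && cur_i == ci0 && cur_j == cj0 && found == first_dir)
      break;
    if (first_dir < 0) first_dir = found;
    int ni = cur_i + mr[found], nj = cur_j + mc[found];
    if (!(ni == ci0 && nj == cj0)) { ri.push_back(ni); ci.push_back(nj); }
    back = (found + 4) % 8;  // backtrack = direction to the previous pixel
    cur_i = ni; cur_j = nj;
    if (++guard > guard_max) break;
  }
  // de-duplicate consecutive repeats while preserving order of first visits
  // (a pixel may be visited twice on 1-px-wide spurs; keep all visits except
  // exact consecutive duplicates)
  IntegerMatrix out(ri.size(), 2);
  for (size_t t = 0; t < ri.size(); ++t) {
    out(t, 0) = ri[t];
    out(t, 1) = ci[t];
  }
  return out;
}
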