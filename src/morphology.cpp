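#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Binary morphology and component labeling on logical matrices.
// Pixels outside the image are background; structuring elements are
// logical matrices with odd dimensions, anchored at their centre.

// [[Rcpp::export(name = ".cpp_erode")]]
LogicalMatrix cpp_erode(const LogicalMatrix& x, const LogicalMatrix& se) {
  const int nr = x.nrow(), nc = x.ncol();
  const int kr = se.nrow(), kc = se.ncol();
  const int ar = kr / 2, ac = kc / 2;  // anchor
  LogicalMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      bool keep = true;
      for (int sj = 0; sj < kc && keep; ++sj) {
        for (int si = 0; si < kr; ++si) {
          if (!se(si, sj)) continue;
          const int ii = i + si - ar, jj = j + sj - ac;
          if (ii < 0 || ii >= nr || jj < 0 || jj >= nc || !x(ii, jj)) {
            keep = false;
            break;
          }
        }
      }
      out(i, j) = keep;
    }
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_dilate")]]
LogicalMatrix cpp_dilate(const LogicalMatrix& x, const LogicalMatrix& se) {
  const int nr = x.nrow(), nc = x.ncol();
  const int kr = se.nrow(), kc = se.ncol();
  const int ar = kr / 2, ac = kc / 2;
  LogicalMatrix out(nr, nc);
  // Minkowski sum: paint the (reflected) element over every foreground pixel.
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!x(i, j)) continue;
      for (int sj = 0; sj < kc; ++sj) {
        for (int si = 0; si < kr; ++si) {
          if (!se(si, sj)) continue;
          const int ii = i + si - ar, jj = j + sj - ac;
          if (ii >= 0 && ii < nr && jj >= 0 && jj < nc) out(ii, jj) = true;
        }
      }
    }
  }
  return out;
}

// Connected-component labeling by breadth-first search.
// Labels are assigned in raster (column-major) order of first encounter,
// starting at 1; background pixels get 0.
// [[Rcpp::export(name = ".cpp_label")]]
IntegerMatrix cpp_label(const LogicalMatrix& x, const int connectivity) {
  const int nr = x.nrow(), nc = x.ncol();
  IntegerMatrix lab(nr, nc);
  const int di8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dj8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nnb = (connectivity == 8) ? 8 : 4;
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!x(i, j) || lab(i, j) != 0) continue;
      lab(i, j) = ++next;
      q.push(std::make_pair(i, j));
      while (!q.empty()) {
        const std::pair<int, int> p = q.front();
        q.pop();
        for (int k = 0; k < nnb; ++k) {
          const int ii = p.first + di8[k], jj = p.second + dj8[k];
          if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
          if (x(ii, jj) && lab(ii, jj) == 0) {
            lab(ii, jj) = next;
            q.push(std::make_pair(ii, jj));
          }
        }
      }
    }
  }
  return lab;
}
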