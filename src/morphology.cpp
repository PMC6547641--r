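#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Binary morphology and component labelling on logical matrices.
// Matrices are column-major (R layout); pixel (i, j) = row i, col j, 0-based
// here, 1-based on the R side.

static inline int idx(int i, int j, int nr) { return i + j * nr; }

// Breadth-first labelling of connected components.
// connectivity: 8 (default for foreground objects) or 4 (hole detection).
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(const LogicalMatrix& mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  stack.reserve(1024);
  const int di8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dj8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nnb = (connectivity == 8) ? 8 : 4;
  int next = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      stack.push_back(idx(i, j, nr));
      while (!stack.empty()) {
        int p = stack.back();
        stack.pop_back();
        int pi = p % nr, pj = p / nr;
        for (int k = 0; k < nnb; ++k) {
          int qi = pi + di8[k], qj = pj + dj8[k];
          if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
          if (mask(qi, qj) && lab(qi, qj) == 0) {
            lab(qi, qj) = next;
            stack.push_back(idx(qi, qj, nr));
          }
        }
      }
    }
  }
  return lab;
}

// Fill interior holes: background is traced 4-connected from the image
// border; any background pixel not reached is enclosed and becomes
// foreground.
// [[Rcpp::export]]
LogicalMatrix cpp_fill_holes(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  std::vector<char> outside(static_cast<size_t>(nr) * nc, 0);
  std::vector<int> stack;
  stack.reserve(2 * (nr + nc));
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if ((i == 0 || i == nr - 1 || j == 0 || j == nc - 1) && !mask(i, j) &&
          !outside[idx(i, j, nr)]) {
        outside[idx(i, j, nr)] = 1;
        stack.push_back(idx(i, j, nr));
      }
  const int di[4] = {-1, 1, 0, 0};
  const int dj[4] = {0, 0, -1, 1};
  while (!stack.empty()) {
    int p = stack.back();
    stack.pop_back();
    int pi = p % nr, pj = p / nr;
    for (int k = 0; k < 4; ++k) {
      int qi = pi + di[k], qj = pj + dj[k];
      if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
      int q = idx(qi, qj, nr);
      if (!mask(qi, qj) && !outside[q]) {
        outside[q] = 1;
        stack.push_back(q);
      }
    }
  }
  LogicalMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      out(i, j) = mask(i, j) || !outside[idx(i, j, nr)];
  return out;
}

// 3x3 square (8-neighbour) dilation, iterated.
// [[Rcpp::export]]
LogicalMatrix cpp_dilate3x3(const LogicalMatrix& mask, int iterations) {
  const int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix cur = clone(mask);
  for (int it = 0; it < iterations; ++it) {
    LogicalMatrix nxt(nr, nc);
    for (int j = 0; j < nc; ++j) {
      int j0 = std::max(0, j - 1), j1 = std::min(nc - 1, j + 1);
      for (int i = 0; i < nr; ++i) {
        if (cur(i, j)) { nxt(i, j) = true; continue; }
        int i0 = std::max(0, i - 1), i1 = std::min(nr - 1, i + 1);
        bool on = false;
        for (int jj = j0; jj <= j1 && !on; ++jj)
          for (int ii = i0; ii <= i1; ++ii)
            if (cur(ii, jj)) { on = true; break; }
        nxt(i, j) = on;
      }
    }
    cur = nxt;
  }
  return cur;
}

// 3x3 square erosion, iterated; pixels beyond the border count as background.
// [[Rcpp::export]]
LogicalMatrix cpp_erode3x3(const LogicalMatrix& mask, int iterations) {
  const int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix cur = clone(mask);
  for (int it = 0; it < iterations; ++it) {
    LogicalMatrix nxt(nr, nc);
    for (int j = 0; j < nc; ++j) {
      for (int i = 0; i < nr; ++i) {
        if (!cur(i, j)) { nxt(i, j) = false; continue; }
        bool on = (i > 0 && i < nr - 1 && j > 0 && j < nc - 1);
        if (on)
          for (int jj = j - 1; jj <= j + 1 && on; ++jj)
            for (int ii = i - 1; ii <= i + 1; ++ii)
              if (!cur(ii, jj)) { on = false; break; }
        nxt(i, j) = on;
      }
    }
    cur = nxt;
  }
  return cur;
}
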