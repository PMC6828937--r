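#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// 8-connectivity connected-component labeling by iterative flood fill.
// Labels are 1..K in raster (column-major) order of first encounter.
// [[Rcpp::export(name = ".cpp_label8", rng = false)]]
IntegerMatrix cpp_label8(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> stack;
  stack.reserve(256);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j)) continue;
      ++next;
      stack.push_back(i + j * nr);
      lab(i, j) = next;
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int ci = idx % nr, cj = idx / nr;
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj) continue;
            int ni = ci + di, nj = cj + dj;
            if (ni < 0 || nj < 0 || ni >= nr || nj >= nc) continue;
            if (mask(ni, nj) && !lab(ni, nj)) {
              lab(ni, nj) = next;
              stack.push_back(ni + nj * nr);
            }
          }
        }
      }
    }
  }
  return lab;
}

// Grayscale erosion by a non-flat structuring element given as offset
// lists (dr, dc) with heights h. Out-of-image offsets are skipped, i.e.
// the image is implicitly padded with +Inf.
// [[Rcpp::export(name = ".cpp_grey_erode", rng = false)]]
NumericMatrix cpp_grey_erode(NumericMatrix img, IntegerVector dr,
                             IntegerVector dc, NumericVector h) {
  int nr = img.nrow(), nc = img.ncol(), K = dr.size();
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double m = R_PosInf;
      for (int k = 0; k < K; ++k) {
        int ni = i + dr[k], nj = j + dc[k];
        if (ni < 0 || nj < 0 || ni >= nr || nj >= nc) continue;
        double v = img(ni, nj) - h[k];
        if (v < m) m = v;
      }
      out(i, j) = m;
    }
  }
  return out;
}

// Grayscale dilation by the same element (reflected handled by caller
// passing symmetric offsets). Out-of-image offsets skipped (-Inf pad).
// [[Rcpp::export(name = ".cpp_grey_dilate", rng = false)]]
NumericMatrix cpp_grey_dilate(NumericMatrix img, IntegerVector dr,
                              IntegerVector dc, NumericVector h) {
  int nr = img.nrow(), nc = img.ncol(), K = dr.size();
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double m = R_NegInf;
      for (int k = 0; k < K; ++k) {
        int ni = i - dr[k], nj = j - dc[k];
        if (ni < 0 || nj < 0 || ni >= nr || nj >= nc) continue;
        double v = img(ni, nj) + h[k];
        if (v > m) m = v;
      }
      out(i, j) = m;
    }
  }
  return out;
}

// Outer-contour perimeter of every labeled region by Moore-neighbour
// boundary tracing with Jacob's stopping criterion; axial steps weigh 1,
// diagonal steps sqrt(2). Single-pixel regions return 0.
// [[Rcpp::export(name = ".cpp_region_perimeters", rng = false)]]
NumericVector cpp_region_perimeters(IntegerMatrix lab, int nlab) {
  int nr = lab.nrow(), nc = lab.ncol();
  NumericVector per(nlab);
  // start pixel per label: first in column-major scan
  std::vector<int> start(nlab + 1, -1);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      int L = lab(i, j);
      if (L > 0 && start[L] < 0) start[L] = i + j * nr;
    }
  // Moore neighbourhood in clockwise order starting from W
  const int mdi[8] = {0, -1, -1, -1, 0, 1, 1, 1};
  const int mdj[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
  const double mlen[8] = {1.0, M_SQRT2, 1.0, M_SQRT2, 1.0, M_SQRT2, 1.0,
                          M_SQRT2};
  for (int L = 1; L <= nlab; ++L) {
    if (start[L] < 0) { per[L - 1] = NA_REAL; continue; }
    int si = start[L] % nr, sj = start[L] / nr;
    // isolated pixel?
    bool iso = true;
    for (int k = 0; k < 8 && iso; ++k) {
      int ni = si + mdi[k], nj = sj + mdj[k];
      if (ni >= 0 && nj >= 0 && ni < nr && nj < nc && lab(ni, nj) == L)
        iso = false;
    }
    if (iso) { per[L - 1] = 0.0; continue; }
    double total = 0.0;
    int ci = si, cj = sj;
    // backtrack direction: came from W (column-major scan found the
    // topmost pixel of the leftmost column, so W and N are background)
    int bdir = 0;  // index into moore order of the backtrack neighbour
    int firstdir = -1;
    long guard = 0, maxsteps = 8L * nr * nc;
    while (guard++ < maxsteps) {
      int found = -1;
      for (int s = 1; s <= 8; ++s) {
        int k = (bdir + s) % 8;
        int ni = ci + mdi[k], nj = cj + mdj[k];
        if (ni >= 0 && nj >= 0 && ni < nr && nj < nc && lab(ni, nj) == L) {
          found = k;
          break;
        }
      }
      if (found < 0) break;  // should not happen (not isolated)
      if (ci == si && cj == sj) {
        if (firstdir < 0) firstdir = found;
        else if (found == firstdir && total > 0) break;  // Jacob's criterion
      }
      total += mlen[found];
      // move; next radial sweep starts just past the direction pointing
      // back at the pixel we came from
      int ni = ci + mdi[found], nj = cj + mdj[found];
      bdir = (found + 4) % 8;
      ci = ni; cj = nj;
    }
    per[L - 1] = total;
  }
  return per;
}
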