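// Binary-mask utilities that need exact, specified semantics:
// 8-connected component labelling and the symmetric Hausdorff distance
// between mask contours (a contour pixel is a foreground pixel with at
// least one 4-neighbour outside the mask; pixels on the image border with
// foreground value count their out-of-grid neighbours as background).

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
IntegerMatrix cpp_label8(IntegerMatrix m) {
  int H = m.nrow(), W = m.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> stack;
  int next = 0;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      if (m[i + (size_t)H * j] == 0 || lab[i + (size_t)H * j] != 0) continue;
      ++next;
      stack.push_back(i + H * j);
      lab[i + (size_t)H * j] = next;
      while (!stack.empty()) {
        int p = stack.back();
        stack.pop_back();
        int pi = p % H, pj = p / H;
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0) continue;
            int qi = pi + di, qj = pj + dj;
            if (qi < 0 || qi >= H || qj < 0 || qj >= W) continue;
            size_t q = qi + (size_t)H * qj;
            if (m[q] != 0 && lab[q] == 0) {
              lab[q] = next;
              stack.push_back((int)q);
            }
          }
      }
    }
  return lab;
}

static void contour_points(const IntegerMatrix& m, std::vector<double>& ri,
                           std::vector<double>& rj) {
  int H = m.nrow(), W = m.ncol();
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      if (m[i + (size_t)H * j] == 0) continue;
      bool edge = (i == 0 || m[i - 1 + (size_t)H * j] == 0) ||
                  (i == H - 1 || m[i + 1 + (size_t)H * j] == 0) ||
                  (j == 0 || m[i + (size_t)H * (j - 1)] == 0) ||
                  (j == W - 1 || m[i + (size_t)H * (j + 1)] == 0);
      if (edge) { ri.push_back(i); rj.push_back(j); }
    }
}

static double directed_hd(const std::vector<double>& ai,
                          const std::vector<double>& aj,
                          const std::vector<double>& bi,
                          const std::vector<double>& bj) {
  double hmax = 0;
  for (size_t p = 0; p < ai.size(); ++p) {
    double best = R_PosInf;
    for (size_t q = 0; q < bi.size(); ++q) {
      double di = ai[p] - bi[q], dj = aj[p] - bj[q];
      double d2 = di * di + dj * dj;
      if (d2 < best) {
        best = d2;
        if (best <= hmax) break;   // cannot raise the running maximum
      }
    }
    if (best > hmax) hmax = best;
  }
  return std::sqrt(hmax);
}

// [[Rcpp::export]]
double cpp_hausdorff(IntegerMatrix a, IntegerMatrix b) {
  if (a.nrow() != b.nrow() || a.ncol() != b.ncol())
    stop("masks must have identical dimensions");
  std::vector<double> ai, aj, bi, bj;
  contour_points(a, ai, aj);
  contour_points(b, bi, bj);
  if (ai.empty() || bi.empty()) return NA_REAL;
  return std::max(directed_hd(ai, aj, bi, bj), directed_hd(bi, bj, ai, aj));
}
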