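#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// 8-connected labeling of foreground (nonzero) pixels by iterative flood
// fill in raster-scan order, so labels are 1..u and deterministic.
// [[Rcpp::export(name = ".label8")]]
IntegerMatrix label8(const IntegerMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  stack.reserve(256);
  int next = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (mask(i, j) == 0 || lab(i, j) != 0) continue;
      ++next;
      stack.push_back(i + j * nr);
      lab(i, j) = next;
      while (!stack.empty()) {
        const int p = stack.back();
        stack.pop_back();
        const int pi = p % nr, pj = p / nr;
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0) continue;
            const int qi = pi + di, qj = pj + dj;
            if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
            if (mask(qi, qj) != 0 && lab(qi, qj) == 0) {
              lab(qi, qj) = next;
              stack.push_back(qi + qj * nr);
            }
          }
        }
      }
    }
  }
  return lab;
}

// Background (zero) pixels 4-connected to the image border. The complement
// over background pixels is the set of enclosed holes.
// [[Rcpp::export(name = ".borderBackground4")]]
LogicalMatrix borderBackground4(const IntegerMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix reach(nr, nc);
  std::vector<int> stack;
  stack.reserve(2 * (nr + nc));
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      const bool border = (i == 0 || i == nr - 1 || j == 0 || j == nc - 1);
      if (border && mask(i, j) == 0 && !reach(i, j)) {
        reach(i, j) = true;
        stack.push_back(i + j * nr);
      }
    }
  }
  const int di[4] = {-1, 1, 0, 0};
  const int dj[4] = {0, 0, -1, 1};
  while (!stack.empty()) {
    const int p = stack.back();
    stack.pop_back();
    const int pi = p % nr, pj = p / nr;
    for (int d = 0; d < 4; ++d) {
      const int qi = pi + di[d], qj = pj + dj[d];
      if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
      if (mask(qi, qj) == 0 && !reach(qi, qj)) {
        reach(qi, qj) = true;
        stack.push_back(qi + qj * nr);
      }
    }
  }
  return reach;
}
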