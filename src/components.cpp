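#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labeling of the zero (missing-seedling) cells of a
// 0/1 emergence matrix. Labels are assigned 1..k in row-major
// first-encounter order; emerged cells keep label 0.
//
// [[Rcpp::export]]
List label_components_cpp(const IntegerMatrix& cells, int connectivity) {
  const int nr = cells.nrow(), nc = cells.ncol();
  IntegerMatrix labels(nr, nc);

  static const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  static const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int ndir = (connectivity == 4) ? 4 : 8;

  std::vector<int> stack;
  stack.reserve(64);
  int nlab = 0;

  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      if (cells(i, j) != 0 || labels(i, j) != 0) continue;
      ++nlab;
      labels(i, j) = nlab;
      stack.push_back(i + j * nr);
      while (!stack.empty()) {
        const int idx = stack.back();
        stack.pop_back();
        const int ci = idx % nr, cj = idx / nr;
        for (int d = 0; d < ndir; ++d) {
          const int ni = ci + dr8[d], nj = cj + dc8[d];
          if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
          if (cells(ni, nj) == 0 && labels(ni, nj) == 0) {
            labels(ni, nj) = nlab;
            stack.push_back(ni + nj * nr);
          }
        }
      }
    }
  }
  return List::create(_["labels"] = labels, _["n_spots"] = nlab);
}

// Component count only (no labels matrix kept) -- used by replicate sweeps.
//
// [[Rcpp::export]]
int count_components_cpp(const IntegerMatrix& cells, int connectivity) {
  List res = label_components_cpp(cells, connectivity);
  return as<int>(res["n_spots"]);
}
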