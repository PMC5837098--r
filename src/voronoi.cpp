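#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Clipped Voronoi nutrition areas for the emerged plants of a 0/1 grid.
//
// Plants sit at cell centers: x = (j + 1/2) * plant_sp, y = (i + 1/2) *
// row_sp; the field is the rectangle [0, nc*plant_sp] x [0, nr*row_sp].
// Each plant's cell is obtained by Sutherland-Hodgman clipping of the
// field rectangle with the perpendicular-bisector half-planes of nearby
// emerged plants. Starting from the bounded rectangle is equivalent to
// the mirror-point construction (reflections across the field edges
// generate exactly the edge half-planes), and a full regular grid
// partitions the field into exact spacing rectangles.
//
// Neighbor search: candidate plants are gathered in expanding
// anisotropic boxes whose physical reach grows by max(row_sp, plant_sp)
// per step, sorted by distance, and clipped nearest-first. A plant at
// distance d cuts the current cell only if d < 2 * max vertex distance,
// which prunes almost all candidates; once the guaranteed minimum
// distance outside the box exceeds that bound the search stops.

struct Workspace {
  std::vector<double> px_, py_, qx_, qy_;  // polygon double-buffer
  std::vector<double> cd2_, cx_, cy_;      // candidate distances/coords
  std::vector<int> order_;
};

// keep the side a*x + b*y <= c; reads (px_, py_), writes via swap
static void clip_halfplane(Workspace& w, double a, double b, double c) {
  const size_t n = w.px_.size();
  w.qx_.clear();
  w.qy_.clear();
  for (size_t k = 0; k < n; ++k) {
    const size_t k2 = (k + 1 == n) ? 0 : k + 1;
    const double f1 = a * w.px_[k] + b * w.py_[k] - c;
    const double f2 = a * w.px_[k2] + b * w.py_[k2] - c;
    if (f1 <= 0) {
      w.qx_.push_back(w.px_[k]);
      w.qy_.push_back(w.py_[k]);
    }
    if ((f1 < 0 && f2 > 0) || (f1 > 0 && f2 < 0)) {
      const double t = f1 / (f1 - f2);
      w.qx_.push_back(w.px_[k] + t * (w.px_[k2] - w.px_[k]));
      w.qy_.push_back(w.py_[k] + t * (w.py_[k2] - w.py_[k]));
    }
  }
  w.px_.swap(w.qx_);
  w.py_.swap(w.qy_);
}

static double poly_area(const Workspace& w) {
  const size_t n = w.px_.size();
  double s = 0.0;
  for (size_t k = 0; k < n; ++k) {
    const size_t k2 = (k + 1 == n) ? 0 : k + 1;
    s += w.px_[k] * w.py_[k2] - w.px_[k2] * w.py_[k];
  }
  return 0.5 * std::fabs(s);
}

static double max_dist2(const Workspace& w, double px, double py) {
  double m = 0.0;
  for (size_t k = 0; k < w.px_.size(); ++k) {
    const double dx = w.px_[k] - px, dy = w.py_[k] - py;
    const double d2 = dx * dx + dy * dy;
    if (d2 > m) m = d2;
  }
  return m;
}

// [[Rcpp::export]]
NumericVector voronoi_areas_cpp(const IntegerMatrix& cells,
                                double row_sp, double plant_sp) {
  const int nr = cells.nrow(), nc = cells.ncol();
  const double W = nc * plant_sp, H = nr * row_sp;
  const double step = (row_sp > plant_sp) ? row_sp : plant_sp;

  int n_plants = 0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (cells(i, j) != 0) ++n_plants;
  NumericVector areas(n_plants);
  if (n_plants == 0) return areas;

  Workspace w;
  int out = 0;
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      if (cells(i, j) == 0) continue;
      const double px = (j + 0.5) * plant_sp, py = (i + 0.5) * row_sp;
      w.px_ = {0.0, W, W, 0.0};
      w.py_ = {0.0, 0.0, H, H};
      double maxd2 = max_dist2(w, px, py);

      int pbi = 0, pbj = 0;  // previous box half-extents
      for (int t = 1;; ++t) {
        const double R = t * step;
        const int bi = (int)std::ceil(R / row_sp);
        const int bj = (int)std::ceil(R / plant_sp);

        // gather new emerged candidates in box t \ box t-1
        w.cd2_.clear();
        w.cx_.clear();
        w.cy_.clear();
        for (int di = -bi; di <= bi; ++di) {
          const int ii = i + di;
          if (ii < 0 || ii >= nr) continue;
          const bool inner_row = (t > 1) && (di >= -pbi && di <= pbi);
          for (int dj = -bj; dj <= bj; ++dj) {
            if (di == 0 && dj == 0) continue;
            if (inner_row && dj >= -pbj && dj <= pbj) continue;
            const int jj = j + dj;
            if (jj < 0 || jj >= nc) continue;
            if (cells(ii, jj) == 0) continue;
            const double sx = (jj + 0.5) * plant_sp;
            const double sy = (ii + 0.5) * row_sp;
            const double dx = sx - px, dy = sy - py;
            w.cd2_.push_back(dx * dx + dy * dy);
            w.cx_.push_back(sx);
            w.cy_.push_back(sy);
          }
        }
        const int ncand = (int)w.cd2_.size();
        w.order_.resize(ncand);
        for (int k = 0; k < ncand; ++k) w.order_[k] = k;
        std::sort(w.order_.begin(), w.order_.end(),
                  [&](int a, int b) { return w.cd2_[a] < w.cd2_[b]; });

        for (int k = 0; k < ncand; ++k) {
          const int c = w.order_[k];
          if (w.cd2_[c] >= 4.0 * maxd2) break;  // sorted: rest is farther
          const double sx = w.cx_[c], sy = w.cy_[c];
          // |q-p|^2 <= |q-s|^2  <=>  2(s-p).q <= |s|^2 - |p|^2
          clip_halfplane(w, 2.0 * (sx - px), 2.0 * (sy - py),
                         sx * sx - px * px + sy * sy - py * py);
          maxd2 = max_dist2(w, px, py);
        }

        if (R * R >= 4.0 * maxd2) break;  // nothing outside can cut
        if (i - bi < 0 && i + bi >= nr && j - bj < 0 && j + bj >= nc)
          break;  // box already covers the whole lattice
        pbi = bi;
        pbj = bj;
      }
      areas[out++] = poly_area(w);
    }
  }
  return areas;
}
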