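#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Uniform grid hash over the population's bounding volume, used for O(1)
// soma-overlap queries while the random walk runs.
struct Grid {
  double cell, x0, y0, z0;
  int nx, ny, nz;
  std::vector<std::vector<int> > bins;
  std::vector<double> px, py, pz;
  std::vector<int> sub;  // sublayer index per point (placement use only)

  Grid(double cell_, double x0_, double x1, double y0_, double y1,
       double z0_, double z1)
      : cell(cell_), x0(x0_), y0(y0_), z0(z0_) {
    nx = std::max(1, (int)std::ceil((x1 - x0) / cell));
    ny = std::max(1, (int)std::ceil((y1 - y0) / cell));
    nz = std::max(1, (int)std::ceil((z1 - z0) / cell));
    bins.resize((size_t)nx * ny * nz);
  }
  int idx(double x, double y, double z) const {
    int ix = std::min(nx - 1, std::max(0, (int)((x - x0) / cell)));
    int iy = std::min(ny - 1, std::max(0, (int)((y - y0) / cell)));
    int iz = std::min(nz - 1, std::max(0, (int)((z - z0) / cell)));
    return (ix * ny + iy) * nz + iz;
  }
  void insert(double x, double y, double z, int s = 0) {
    px.push_back(x); py.push_back(y); pz.push_back(z);
    sub.push_back(s);
    bins[idx(x, y, z)].push_back((int)px.size() - 1);
  }
  // Overlap rule of the walk: within the candidate's own sublayer the
  // in-plane (x, z) distance must be >= min_d (the cells are laid out in 2D
  // there); against every other sublayer the full 3D distance applies.
  // y_span widens the vertical search window to the sublayer height.
  bool overlaps(double x, double y, double z, double min_d, int s = -1,
                double y_span = 0.0) const {
    double d2 = min_d * min_d;
    int ix = std::min(nx - 1, std::max(0, (int)((x - x0) / cell)));
    int iy = std::min(ny - 1, std::max(0, (int)((y - y0) / cell)));
    int iz = std::min(nz - 1, std::max(0, (int)((z - z0) / cell)));
    int r = (int)std::ceil(min_d / cell);
    int ry = (int)std::ceil((min_d + y_span) / cell);
    for (int a = std::max(0, ix - r); a <= std::min(nx - 1, ix + r); ++a)
      for (int b = std::max(0, iy - ry); b <= std::min(ny - 1, iy + ry); ++b)
        for (int c = std::max(0, iz - r); c <= std::min(nz - 1, iz + r); ++c) {
          const std::vector<int>& v = bins[(a * ny + b) * nz + c];
          for (size_t k = 0; k < v.size(); ++k) {
            double dx = px[v[k]] - x, dy = py[v[k]] - y, dz = pz[v[k]] - z;
            double dxz2 = dx * dx + dz * dz;
            if (s >= 0 && sub[v[k]] == s) {
              if (dxz2 < d2) return true;
            } else if (dxz2 + dy * dy < d2) {
              return true;
            }
          }
        }
    return false;
  }
};

static double draw_step(double eps) {
  // normal centred on eps, truncated to [0.75 eps, 1.25 eps]
  double lo = 0.75 * eps, hi = 1.25 * eps, s;
  for (int k = 0; k < 20; ++k) {
    s = R::rnorm(eps, eps / 8.0);
    if (s >= lo && s <= hi) return s;
  }
  return eps;
}

// Bounded self-avoiding random walk over stacked sublayers.  Each sublayer
// receives n_target[s] somata; candidates advance from the previous soma by
// (2 r + step) along a uniform planar angle, with the vertical coordinate
// drawn uniformly inside the sublayer; a candidate overlapping any placed
// soma of the population (in-plane rule within its sublayer, 3D rule against
// the other sublayers -- see Grid::overlaps) or leaving the base rectangle
// is redrawn up to max_tries times, after which the walk
// restarts from a fresh uniform point.  Walks also restart after segment_max
// accepted placements: finite segments keep the walk's local spacing
// statistics while uniformly scattered segment origins give uniform global
// occupancy even for sparse populations, whose walks would otherwise
// diffuse into local clouds.  A sublayer is declared saturated
// after max_restarts *consecutive* restarts that fail to place any cell
// (the counter resets on every successful placement).
// [[Rcpp::export]]
NumericMatrix walk_place_cpp(double base_x, double base_z,
                             NumericVector sub_lo, NumericVector sub_hi,
                             IntegerVector n_target, double r, double eps,
                             int max_tries, int max_restarts,
                             int segment_max) {
  int nsub = sub_lo.size();
  long total_target = 0;
  for (int s = 0; s < nsub; ++s) total_target += n_target[s];

  double y_min = sub_lo[0], y_max = sub_hi[nsub - 1];
  double cell = std::max(2.0 * r, 1.0);
  Grid grid(cell, 0.0, base_x, y_min, y_max, 0.0, base_z);
  grid.px.reserve(total_target);
  double min_d = 2.0 * r;

  for (int s = 0; s < nsub; ++s) {
    int placed = 0, restarts = 0, seg = 0;
    double lo = sub_lo[s], hi = sub_hi[s];
    bool have_prev = false;
    double cx = 0, cz = 0;
    while (placed < n_target[s]) {
      bool ok = false;
      double x, y, z;
      if (seg >= segment_max) { have_prev = false; seg = 0; }
      if (have_prev) {
        for (int t = 0; t < max_tries; ++t) {
          double ang = R::runif(0.0, 2.0 * M_PI);
          double d = min_d + draw_step(eps);
          x = cx + d * std::cos(ang);
          z = cz + d * std::sin(ang);
          y = R::runif(lo, hi);
          if (x < 0 || x > base_x || z < 0 || z > base_z) continue;
          if (!grid.overlaps(x, y, z, min_d, s, hi - lo)) { ok = true; break; }
        }
      }
      if (!ok) {
        // fresh uniform starting point, resetting the walk
        if (have_prev) {
          ++restarts;
          if (restarts > max_restarts) break;  // sublayer saturated
        }
        for (int t = 0; t < max_tries; ++t) {
          x = R::runif(0.0, base_x);
          z = R::runif(0.0, base_z);
          y = R::runif(lo, hi);
          if (!grid.overlaps(x, y, z, min_d, s, hi - lo)) { ok = true; break; }
        }
        if (!ok) {
          ++restarts;
          if (restarts > max_restarts) break;
          continue;
        }
      }
      grid.insert(x, y, z, s);
      cx = x; cz = z; have_prev = true;
      ++placed; ++seg;
      restarts = 0;
    }
  }

  int n = (int)grid.px.size();
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    out(i, 0) = grid.px[i];
    out(i, 1) = grid.py[i];
    out(i, 2) = grid.pz[i];
  }
  return out;
}

// All (i, j) pairs with |A_i - B_j| <= radius (3D), 1-based indices.
// [[Rcpp::export]]
List radius_pairs_cpp(NumericMatrix A, NumericMatrix B, double radius) {
  int m = B.nrow();
  double x0 = R_PosInf, x1 = R_NegInf, y0 = R_PosInf, y1 = R_NegInf,
         z0 = R_PosInf, z1 = R_NegInf;
  for (int j = 0; j < m; ++j) {
    x0 = std::min(x0, B(j, 0)); x1 = std::max(x1, B(j, 0));
    y0 = std::min(y0, B(j, 1)); y1 = std::max(y1, B(j, 1));
    z0 = std::min(z0, B(j, 2)); z1 = std::max(z1, B(j, 2));
  }
  if (m == 0 || A.nrow() == 0)
    return List::create(_["i"] = IntegerVector(0), _["j"] = IntegerVector(0),
                        _["dist"] = NumericVector(0));
  Grid grid(std::max(radius, 1.0), x0, x1 + 1e-9, y0, y1 + 1e-9, z0, z1 + 1e-9);
  std::vector<std::vector<int> >& bins = grid.bins;
  for (int j = 0; j < m; ++j)
    bins[grid.idx(B(j, 0), B(j, 1), B(j, 2))].push_back(j);

  std::vector<int> ii, jj;
  std::vector<double> dd;
  double r2 = radius * radius;
  for (int i = 0; i < A.nrow(); ++i) {
    double x = A(i, 0), y = A(i, 1), z = A(i, 2);
    int ix = std::min(grid.nx - 1, std::max(0, (int)((x - grid.x0) / grid.cell)));
    int iy = std::min(grid.ny - 1, std::max(0, (int)((y - grid.y0) / grid.cell)));
    int iz = std::min(grid.nz - 1, std::max(0, (int)((z - grid.z0) / grid.cell)));
    for (int a = std::max(0, ix - 1); a <= std::min(grid.nx - 1, ix + 1); ++a)
      for (int b = std::max(0, iy - 1); b <= std::min(grid.ny - 1, iy + 1); ++b)
        for (int c = std::max(0, iz - 1); c <= std::min(grid.nz - 1, iz + 1); ++c) {
          const std::vector<int>& v = bins[(a * grid.ny + b) * grid.nz + c];
          for (size_t k = 0; k < v.size(); ++k) {
            int j = v[k];
            double dx = B(j, 0) - x, dy = B(j, 1) - y, dz = B(j, 2) - z;
            double d2 = dx * dx + dy * dy + dz * dz;
            if (d2 <= r2) {
              ii.push_back(i + 1); jj.push_back(j + 1);
              dd.push_back(std::sqrt(d2));
            }
          }
        }
  }
  return List::create(_["i"] = wrap(ii), _["j"] = wrap(jj), _["dist"] = wrap(dd));
}
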