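#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Piecewise-constant kernel lookup. Radii below the first edge clamp to the
// first bin; radii at/beyond the last edge return 0. `inv_dr > 0` marks
// uniform bin widths and enables O(1) indexing.
static inline double kernel_lookup(double r, const double* edges, const double* dose,
                                   int n, double inv_dr) {
  if (r >= edges[n]) return 0.0;
  if (r < edges[0]) return dose[0];
  int idx;
  if (inv_dr > 0.0) {
    idx = (int)((r - edges[0]) * inv_dr);
    if (idx >= n) idx = n - 1;
    // guard against rounding at bin boundaries
    if (r < edges[idx]) --idx;
    else if (r >= edges[idx + 1]) ++idx;
  } else {
    idx = (int)(std::upper_bound(edges, edges + n + 1, r) - edges) - 1;
    if (idx >= n) return 0.0;
  }
  return dose[idx];
}

// Sum of kernel values over all GNPs, per integration point. Positions in
// micrometres, kernel radii in nanometres. method: 0 = grid cell list
// (radius query), 1 = brute-force all pairs.
// [[Rcpp::export(name = ".superpose_excess_cpp")]]
NumericVector superpose_excess_cpp(NumericVector px, NumericVector py, NumericVector pz,
                                   NumericVector gx, NumericVector gy, NumericVector gz,
                                   NumericVector edges_nm, NumericVector dose_per_bin,
                                   bool uniform_bins, int method) {
  const int np = px.size();
  const int ng = gx.size();
  const int nb = dose_per_bin.size();
  const double* edges = edges_nm.begin();
  const double* dose = dose_per_bin.begin();
  const double rmax_nm = edges_nm[nb];
  const double rmax_um = rmax_nm / 1000.0;
  const double rmax2 = rmax_um * rmax_um;
  double inv_dr = uniform_bins ? 1.0 / (edges_nm[1] - edges_nm[0]) : -1.0;

  NumericVector out(np);
  if (ng == 0) return out;

  if (method == 1) { // brute force all pairs
    for (int i = 0; i < np; ++i) {
      double s = 0.0;
      for (int j = 0; j < ng; ++j) {
        double dx = px[i] - gx[j], dy = py[i] - gy[j], dz = pz[i] - gz[j];
        double r2 = dx * dx + dy * dy + dz * dz;
        if (r2 >= rmax2) continue;
        s += kernel_lookup(std::sqrt(r2) * 1000.0, edges, dose, nb, inv_dr);
      }
      out[i] = s;
    }
    return out;
  }

  // Grid cell list over GNPs, cell size rmax/2: for each point only cells
  // intersecting the rmax ball are visited.
  const double h = rmax_um / 2.0;
  double xmin = *std::min_element(gx.begin(), gx.end());
  double ymin = *std::min_element(gy.begin(), gy.end());
  double zmin = *std::min_element(gz.begin(), gz.end());
  double xmax = *std::max_element(gx.begin(), gx.end());
  double ymax = *std::max_element(gy.begin(), gy.end());
  double zmax = *std::max_element(gz.begin(), gz.end());
  int nx = std::max(1, (int)std::floor((xmax - xmin) / h) + 1);
  int ny = std::max(1, (int)std::floor((ymax - ymin) / h) + 1);
  int nz = std::max(1, (int)std::floor((zmax - zmin) / h) + 1);

  std::vector<int> counts((size_t)nx * ny * nz, 0);
  std::vector<int> cell_of(ng);
  for (int j = 0; j < ng; ++j) {
    int cx = std::min(nx - 1, (int)((gx[j] - xmin) / h));
    int cy = std::min(ny - 1, (int)((gy[j] - ymin) / h));
    int cz = std::min(nz - 1, (int)((gz[j] - zmin) / h));
    int c = (cx * ny + cy) * nz + cz;
    cell_of[j] = c;
    ++counts[c];
  }
  std::vector<int> start(counts.size() + 1, 0);
  for (size_t c = 0; c < counts.size(); ++c) start[c + 1] = start[c] + counts[c];
  // GNP coordinates reordered cell-contiguously for sequential scans
  std::vector<double> sgx(ng), sgy(ng), sgz(ng);
  std::vector<int> fill(start.begin(), start.end() - 1);
  for (int j = 0; j < ng; ++j) {
    int pos = fill[cell_of[j]]++;
    sgx[pos] = gx[j]; sgy[pos] = gy[j]; sgz[pos] = gz[j];
  }

  for (int i = 0; i < np; ++i) {
    double s = 0.0;
    int cx0 = std::max(0, (int)std::floor((px[i] - rmax_um - xmin) / h));
    int cx1 = std::min(nx - 1, (int)std::floor((px[i] + rmax_um - xmin) / h));
    int cy0 = std::max(0, (int)std::floor((py[i] - rmax_um - ymin) / h));
    int cy1 = std::min(ny - 1, (int)std::floor((py[i] + rmax_um - ymin) / h));
    int cz0 = std::max(0, (int)std::floor((pz[i] - rmax_um - zmin) / h));
    int cz1 = std::min(nz - 1, (int)std::floor((pz[i] + rmax_um - zmin) / h));
    for (int cx = cx0; cx <= cx1; ++cx)
      for (int cy = cy0; cy <= cy1; ++cy)
        for (int cz = cz0; cz <= cz1; ++cz) {
          int c = (cx * ny + cy) * nz + cz;
          for (int k = start[c]; k < start[c + 1]; ++k) {
            double dx = px[i] - sgx[k], dy = py[i] - sgy[k], dz = pz[i] - sgz[k];
            double r2 = dx * dx + dy * dy + dz * dz;
            if (r2 >= rmax2) continue;
            s += kernel_lookup(std::sqrt(r2) * 1000.0, edges, dose, nb, inv_dr);
          }
        }
    out[i] = s;
  }
  return out;
}

// Random sequential addition of non-overlapping vesicle centres in the
// cytoplasm: centre inside the inner-parallel (shrunken-axis) ellipsoid,
// whole vesicle outside the nucleus, pairwise separation >= 2 r_ves.
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export(name = ".rsa_pack_centers_cpp")]]
NumericMatrix rsa_pack_centers_cpp(int n, double r_ves, double a, double b, double c,
                                   double nucleus_r, int max_consecutive_fail) {
  if (n <= 0) return NumericMatrix(0, 3);
  double sa = a - r_ves, sb = b - r_ves, sc = c - r_ves;
  if (sa <= 0 || sb <= 0 || sc <= 0)
    stop("Vesicle radius exceeds a cell semi-axis; use fewer or smaller vesicles.");
  double rmin = nucleus_r + r_ves;
  double sep2 = 4.0 * r_ves * r_ves;
  double h = 2.0 * r_ves; // grid cell size for the overlap query
  int nx = std::max(1, (int)std::floor(2 * a / h) + 1);
  int ny = std::max(1, (int)std::floor(2 * b / h) + 1);
  int nz = std::max(1, (int)std::floor(2 * c / h) + 1);
  std::vector<std::vector<int> > grid((size_t)nx * ny * nz);

  NumericMatrix out(n, 3);
  GetRNGstate();
  int placed = 0, fails = 0;
  while (placed < n) {
    if (fails > max_consecutive_fail) {
      PutRNGstate();
      stop("Vesicle packing retry budget exceeded; use fewer or smaller vesicles.");
    }
    double x = (2.0 * unif_rand() - 1.0) * a;
    double y = (2.0 * unif_rand() - 1.0) * b;
    double z = (2.0 * unif_rand() - 1.0) * c;
    double e = (x / sa) * (x / sa) + (y / sb) * (y / sb) + (z / sc) * (z / sc);
    if (e > 1.0 || x * x + y * y + z * z < rmin * rmin) { ++fails; continue; }
    int cx = std::min(nx - 1, (int)((x + a) / h));
    int cy = std::min(ny - 1, (int)((y + b) / h));
    int cz = std::min(nz - 1, (int)((z + c) / h));
    bool overlap = false;
    for (int ix = std::max(0, cx - 1); ix <= std::min(nx - 1, cx + 1) && !overlap; ++ix)
      for (int iy = std::max(0, cy - 1); iy <= std::min(ny - 1, cy + 1) && !overlap; ++iy)
        for (int iz = std::max(0, cz - 1); iz <= std::min(nz - 1, cz + 1) && !overlap; ++iz) {
          const std::vector<int>& cell = grid[((size_t)ix * ny + iy) * nz + iz];
          for (size_t k = 0; k < cell.size(); ++k) {
            double dx = x - out(cell[k], 0), dy = y - out(cell[k], 1), dz = z - out(cell[k], 2);
            if (dx * dx + dy * dy + dz * dz < sep2) { overlap = true; break; }
          }
        }
    if (overlap) { ++fails; continue; }
    out(placed, 0) = x; out(placed, 1) = y; out(placed, 2) = z;
    grid[((size_t)cx * ny + cy) * nz + cz].push_back(placed);
    ++placed;
    fails = 0;
  }
  PutRNGstate();
  return out;
}
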