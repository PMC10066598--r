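#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <random>
using namespace Rcpp;

// Point-in-regular-hexagon test. Hexagon centred on (0,0) in the xz plane,
// vertices on the x axis (vertex-to-vertex diagonal = 2 * side).
static inline bool in_hexagon(double x, double z, double side) {
  const double apothem = side * 0.8660254037844386; // side * sqrt(3)/2
  // edge normals at 30, 90, 150 degrees
  const double c30 = 0.8660254037844386, s30 = 0.5;
  if (std::fabs(z) > apothem + 1e-12) return false;
  if (std::fabs(c30 * z + s30 * x) > apothem + 1e-12) return false;
  if (std::fabs(c30 * z - s30 * x) > apothem + 1e-12) return false;
  return true;
}

// [[Rcpp::export]]
LogicalVector cpp_in_hexagon(NumericVector x, NumericVector z, double side) {
  int n = x.size();
  LogicalVector out(n);
  for (int i = 0; i < n; i++) out[i] = in_hexagon(x[i], z[i], side);
  return out;
}

// Dart-throwing Poisson-disc sampling inside a hexagonal prism slab.
// Points are accepted when no previously accepted point lies within
// min_dist (Euclidean, 3D). Sampling stops at n_target accepted points or
// when the attempt budget is exhausted.
// [[Rcpp::export]]
NumericMatrix cpp_poisson_disc_hex(double side, double y0, double y1,
                                   int n_target, double min_dist,
                                   int max_attempts_per_point, int seed) {
  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  const double xr = side;                       // bounding half-width in x
  const double zr = side * 0.8660254037844386;  // in z
  const double h = y1 - y0;

  // uniform grid for neighbour queries
  double cell = std::max(min_dist / std::sqrt(3.0), 1e-6);
  int nx = std::max(1, (int)std::ceil(2 * xr / cell));
  int ny = std::max(1, (int)std::ceil(h / cell));
  int nz = std::max(1, (int)std::ceil(2 * zr / cell));
  std::vector< std::vector<int> > grid((size_t)nx * ny * nz);

  std::vector<double> px, py, pz;
  px.reserve(n_target); py.reserve(n_target); pz.reserve(n_target);

  long long budget = (long long)max_attempts_per_point * (long long)std::max(n_target, 1);
  long long attempts = 0;
  int reach = (int)std::ceil(min_dist / cell);
  const double md2 = min_dist * min_dist;

  while ((int)px.size() < n_target && attempts < budget) {
    attempts++;
    double x = (2 * unif(rng) - 1) * xr;
    double z = (2 * unif(rng) - 1) * zr;
    if (!in_hexagon(x, z, side)) continue;
    double y = y0 + unif(rng) * h;

    int ix = std::min(nx - 1, std::max(0, (int)((x + xr) / cell)));
    int iy = std::min(ny - 1, std::max(0, (int)((y - y0) / cell)));
    int iz = std::min(nz - 1, std::max(0, (int)((z + zr) / cell)));

    bool ok = true;
    for (int dx = -reach; dx <= reach && ok; dx++) {
      int jx = ix + dx; if (jx < 0 || jx >= nx) continue;
      for (int dy = -reach; dy <= reach && ok; dy++) {
        int jy = iy + dy; if (jy < 0 || jy >= ny) continue;
        for (int dz = -reach; dz <= reach && ok; dz++) {
          int jz = iz + dz; if (jz < 0 || jz >= nz) continue;
          const std::vector<int>& bucket = grid[(size_t)jx + (size_t)nx * (jy + (size_t)ny * jz)];
          for (int id : bucket) {
            double ddx = px[id] - x, ddy = py[id] - y, ddz = pz[id] - z;
            if (ddx * ddx + ddy * ddy + ddz * ddz < md2) { ok = false; break; }
          }
        }
      }
    }
    if (!ok) continue;
    int id = (int)px.size();
    px.push_back(x); py.push_back(y); pz.push_back(z);
    grid[(size_t)ix + (size_t)nx * (iy + (size_t)ny * iz)].push_back(id);
  }

  NumericMatrix out((int)px.size(), 3);
  for (int i = 0; i < (int)px.size(); i++) {
    out(i, 0) = px[i]; out(i, 1) = py[i]; out(i, 2) = pz[i];
  }
  out.attr("attempts") = (double)attempts;
  return out;
}
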