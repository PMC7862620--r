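#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Shrake-Rupley solvent-accessible surface area with a fixed golden-spiral
// quadrature lattice.  Deterministic: the lattice depends only on n_points.
//
// coords: n x 3, radii: contact radii (A), probe: probe radius (A).
// Returns per-atom accessible areas (A^2).
// [[Rcpp::export(name = ".sasa_cpp")]]
NumericVector sasa_cpp(NumericMatrix coords, NumericVector radii,
                       double probe, int n_points) {
  const int n = coords.nrow();
  NumericVector area(n);
  if (n == 0) return area;

  // Golden-spiral unit sphere lattice.
  std::vector<double> sx(n_points), sy(n_points), sz(n_points);
  const double golden = M_PI * (3.0 - std::sqrt(5.0));
  for (int k = 0; k < n_points; ++k) {
    double zk = 1.0 - 2.0 * (k + 0.5) / n_points;
    double rk = std::sqrt(std::max(0.0, 1.0 - zk * zk));
    double th = golden * k;
    sx[k] = rk * std::cos(th);
    sy[k] = rk * std::sin(th);
    sz[k] = zk;
  }

  std::vector<double> R(n);
  for (int i = 0; i < n; ++i) R[i] = radii[i] + probe;

  for (int i = 0; i < n; ++i) {
    const double xi = coords(i, 0), yi = coords(i, 1), zi = coords(i, 2);
    const double Ri = R[i];
    // neighbor prefilter: only atoms whose expanded spheres can intersect
    std::vector<int> nb;
    nb.reserve(32);
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = coords(j, 0) - xi, dy = coords(j, 1) - yi,
             dz = coords(j, 2) - zi;
      double d2 = dx * dx + dy * dy + dz * dz;
      double cut = Ri + R[j];
      if (d2 < cut * cut) nb.push_back(j);
    }
    int acc = 0;
    for (int k = 0; k < n_points; ++k) {
      double px = xi + Ri * sx[k], py = yi + Ri * sy[k], pz = zi + Ri * sz[k];
      bool buried = false;
      for (size_t m = 0; m < nb.size(); ++m) {
        int j = nb[m];
        double dx = px - coords(j, 0), dy = py - coords(j, 1),
               dz = pz - coords(j, 2);
        if (dx * dx + dy * dy + dz * dz < R[j] * R[j]) {
          buried = true;
          break;
        }
      }
      if (!buried) ++acc;
    }
    area[i] = 4.0 * M_PI * Ri * Ri * (double)acc / (double)n_points;
  }
  return area;
}
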