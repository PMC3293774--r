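#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Deterministic Fibonacci-lattice points on the unit sphere.  No RNG: the
// lattice is a fixed function of n, so repeated SASA evaluations are
// bit-identical.
static std::vector<double> fib_lattice(int n) {
  std::vector<double> pts(3 * n);
  const double ga = M_PI * (3.0 - std::sqrt(5.0)); // golden angle
  for (int i = 0; i < n; ++i) {
    double z = 1.0 - (2.0 * i + 1.0) / n;
    double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    double th = ga * i;
    pts[3 * i]     = r * std::cos(th);
    pts[3 * i + 1] = r * std::sin(th);
    pts[3 * i + 2] = z;
  }
  return pts;
}

// [[Rcpp::export(name = ".sasa_cpp")]]
NumericVector sasa_cpp(NumericMatrix xyz, NumericVector radii,
                       double probe, int n_points) {
  const int n = xyz.nrow();
  std::vector<double> pts = fib_lattice(n_points);
  NumericVector area(n);

  // expanded radii
  std::vector<double> er(n);
  double rmax = 0.0;
  for (int i = 0; i < n; ++i) {
    er[i] = radii[i] + probe;
    if (er[i] > rmax) rmax = er[i];
  }

  std::vector<int> nbr;
  nbr.reserve(64);
  for (int i = 0; i < n; ++i) {
    const double xi = xyz(i, 0), yi = xyz(i, 1), zi = xyz(i, 2);
    const double ri = er[i];
    // neighbours whose expanded spheres can intersect atom i's
    nbr.clear();
    const double reach = ri + rmax;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = xyz(j, 0) - xi, dy = xyz(j, 1) - yi, dz = xyz(j, 2) - zi;
      double d2 = dx * dx + dy * dy + dz * dz;
      double lim = ri + er[j];
      if (d2 < lim * lim) nbr.push_back(j);
    }
    int acc = 0;
    for (int k = 0; k < n_points; ++k) {
      double px = xi + ri * pts[3 * k];
      double py = yi + ri * pts[3 * k + 1];
      double pz = zi + ri * pts[3 * k + 2];
      bool buried = false;
      for (size_t m = 0; m < nbr.size(); ++m) {
        int j = nbr[m];
        double dx = px - xyz(j, 0), dy = py - xyz(j, 1), dz = pz - xyz(j, 2);
        if (dx * dx + dy * dy + dz * dz < er[j] * er[j]) { buried = true; break; }
      }
      if (!buried) ++acc;
    }
    area[i] = 4.0 * M_PI * ri * ri * (double)acc / (double)n_points;
  }
  return area;
}

// [[Rcpp::export(name = ".clash_cpp")]]
List clash_cpp(NumericMatrix xa, NumericVector ra,
               NumericMatrix xb, NumericVector rb, double tol) {
  const int na = xa.nrow(), nb = xb.nrow();
  int count = 0;
  double worst = 0.0;
  for (int i = 0; i < na; ++i) {
    for (int j = 0; j < nb; ++j) {
      double dx = xa(i, 0) - xb(j, 0);
      double dy = xa(i, 1) - xb(j, 1);
      double dz = xa(i, 2) - xb(j, 2);
      double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      double overlap = ra[i] + rb[j] - d;
      if (overlap > tol) {
        ++count;
        if (overlap > worst) worst = overlap;
      }
    }
  }
  return List::create(_["n_clashing_pairs"] = count,
                      _["worst_overlap"] = worst);
}
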