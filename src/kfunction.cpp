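// Pairwise kernels for the 3-D Ripley K estimator.
//
// Box windows use the translation edge correction
//   w_ij = V / ((Lx - |dx|)(Ly - |dy|)(Lz - |dz|)),
// ball windows the isotropic correction: the reciprocal of the fraction of
// the sphere of radius d_ij centred on point i that lies inside the window
// ball (closed-form spherical-cap area).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector k3_box_counts_cpp(NumericMatrix pts, NumericVector rgrid,
                                NumericVector box) {
  const int n = pts.nrow(), nr = rgrid.size();
  const double Lx = box[0], Ly = box[1], Lz = box[2];
  const double V = Lx * Ly * Lz;
  NumericVector acc(nr);
  for (int i = 0; i < n; ++i) {
    const double xi = pts(i, 0), yi = pts(i, 1), zi = pts(i, 2);
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double dx = std::fabs(pts(j, 0) - xi);
      const double dy = std::fabs(pts(j, 1) - yi);
      const double dz = std::fabs(pts(j, 2) - zi);
      const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (d > rgrid[nr - 1]) continue;
      const double w = V / ((Lx - dx) * (Ly - dy) * (Lz - dz));
      for (int k = nr - 1; k >= 0 && rgrid[k] >= d; --k) acc[k] += w;
    }
  }
  return acc;
}

// window: ball of radius R centred at (cx, cy, cz)
// [[Rcpp::export]]
NumericVector k3_ball_counts_cpp(NumericMatrix pts, NumericVector rgrid,
                                 NumericVector center, double R) {
  const int n = pts.nrow(), nr = rgrid.size();
  NumericVector acc(nr);
  for (int i = 0; i < n; ++i) {
    const double xi = pts(i, 0) - center[0];
    const double yi = pts(i, 1) - center[1];
    const double zi = pts(i, 2) - center[2];
    const double rho = std::sqrt(xi * xi + yi * yi + zi * zi);
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double dx = pts(j, 0) - center[0] - xi;
      const double dy = pts(j, 1) - center[1] - yi;
      const double dz = pts(j, 2) - center[2] - zi;
      const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (d > rgrid[nr - 1] || d == 0.0) continue;
      // fraction of the sphere S(i, d) inside the window ball
      double frac;
      if (rho + d <= R) frac = 1.0;
      else {
        const double cosb = (rho * rho + d * d - R * R) / (2.0 * rho * d);
        frac = 0.5 * (1.0 - cosb);
        if (frac <= 0.0) continue;  // sphere entirely outside (cannot happen for points in window)
      }
      const double w = 1.0 / frac;
      for (int k = nr - 1; k >= 0 && rgrid[k] >= d; --k) acc[k] += w;
    }
  }
  return acc;
}
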