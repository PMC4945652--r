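#include <Rcpp.h>
#include <cmath>

// Analytic Newtonian potential of an axis-aligned cuboid with unit source
// density: I(p) = \iiint_box dV' / |p - r'|  (no 1/(4*pi*sigma) factor here).
//
// The triple antiderivative of 1/r is the classic corner-sum primitive
//   phi(x,y,z) =  x*y*log(z+r) + y*z*log(x+r) + z*x*log(y+r)
//              - x^2/2 * atan(y*z/(x*r))
//              - y^2/2 * atan(z*x/(y*r))
//              - z^2/2 * atan(x*y/(z*r)),   r = sqrt(x^2+y^2+z^2),
// summed over the 8 corner offsets with alternating signs. It is valid for
// field points outside the (closed) box; interior and boundary points are
// handled by splitting the box at the field point, which puts the point at a
// corner of each sub-box where every primitive term vanishes.

namespace {

// log(a + r) computed stably; c2 = r^2 - a^2 (sum of the other two squares).
// When a <= 0 use log(c2) - log(r - a) to avoid catastrophic cancellation.
inline double log_term(double a, double r, double c2) {
  if (a > 0.0) return std::log(a + r);
  double d = r - a;
  if (c2 <= 0.0 || d <= 0.0) return 0.0;  // coefficient is zero in this case
  return std::log(c2) - std::log(d);
}

inline double corner_primitive(double x, double y, double z) {
  double r = std::sqrt(x * x + y * y + z * z);
  if (r == 0.0) return 0.0;
  double v = 0.0;
  if (x != 0.0 && y != 0.0) v += x * y * log_term(z, r, x * x + y * y);
  if (y != 0.0 && z != 0.0) v += y * z * log_term(x, r, y * y + z * z);
  if (z != 0.0 && x != 0.0) v += z * x * log_term(y, r, z * z + x * x);
  if (x != 0.0) v -= 0.5 * x * x * std::atan(y * z / (x * r));
  if (y != 0.0) v -= 0.5 * y * y * std::atan(z * x / (y * r));
  if (z != 0.0) v -= 0.5 * z * z * std::atan(x * y / (z * r));
  return v;
}

// Integral over [x1,x2]x[y1,y2]x[z1,z2] in coordinates relative to the field
// point, assuming the origin is NOT in the open box interior.
inline double box_integral_exterior(double x1, double x2, double y1, double y2,
                                    double z1, double z2) {
  double s = 0.0;
  const double xs[2] = {x1, x2}, ys[2] = {y1, y2}, zs[2] = {z1, z2};
  for (int i = 0; i < 2; ++i)
    for (int j = 0; j < 2; ++j)
      for (int k = 0; k < 2; ++k) {
        double sign = ((i + j + k) % 2 == 0) ? -1.0 : 1.0;  // +1 at (2,2,2)
        s += sign * corner_primitive(xs[i], ys[j], zs[k]);
      }
  return s;
}

// General case: field point anywhere, box given by center and half-edges.
inline double box_integral(double cx, double cy, double cz, double hx,
                           double hy, double hz, double px, double py,
                           double pz) {
  double x1 = cx - hx - px, x2 = cx + hx - px;
  double y1 = cy - hy - py, y2 = cy + hy - py;
  double z1 = cz - hz - pz, z2 = cz + hz - pz;
  bool inside = (x1 < 0.0 && x2 > 0.0) && (y1 < 0.0 && y2 > 0.0) &&
                (z1 < 0.0 && z2 > 0.0);
  if (!inside) return box_integral_exterior(x1, x2, y1, y2, z1, z2);
  // Split at the origin: 8 sub-boxes, each with the singular point at a
  // corner (where the primitive vanishes term-by-term).
  double s = 0.0;
  const double xb[3] = {x1, 0.0, x2}, yb[3] = {y1, 0.0, y2},
               zb[3] = {z1, 0.0, z2};
  for (int i = 0; i < 2; ++i)
    for (int j = 0; j < 2; ++j)
      for (int k = 0; k < 2; ++k)
        s += box_integral_exterior(xb[i], xb[i + 1], yb[j], yb[j + 1], zb[k],
                                   zb[k + 1]);
  return s;
}

}  // namespace

// [[Rcpp::export(name = ".box_potential_cpp")]]
Rcpp::NumericVector box_potential_cpp(Rcpp::NumericVector box_center,
                                      Rcpp::NumericVector box_dims,
                                      Rcpp::NumericMatrix points,
                                      double sigma) {
  int n = points.nrow();
  double hx = box_dims[0] / 2.0, hy = box_dims[1] / 2.0, hz = box_dims[2] / 2.0;
  double scale = 1.0 / (4.0 * M_PI * sigma);
  Rcpp::NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    out[i] = scale * box_integral(box_center[0], box_center[1], box_center[2],
                                  hx, hy, hz, points(i, 0), points(i, 1),
                                  points(i, 2));
  }
  return out;
}

// One z-plane of the leadfield: N electrodes x (nx*ny) cubes, x-fastest.
// [[Rcpp::export(name = ".leadfield_plane_cpp")]]
Rcpp::NumericMatrix leadfield_plane_cpp(Rcpp::NumericVector xc,
                                        Rcpp::NumericVector yc, double zc,
                                        Rcpp::NumericVector dims,
                                        Rcpp::NumericMatrix electrodes,
                                        double sigma) {
  int nx = xc.size(), ny = yc.size(), n_el = electrodes.nrow();
  double hx = dims[0] / 2.0, hy = dims[1] / 2.0, hz = dims[2] / 2.0;
  double scale = 1.0 / (4.0 * M_PI * sigma);
  Rcpp::NumericMatrix out(n_el, nx * ny);
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      int col = j * nx + i;
      for (int n = 0; n < n_el; ++n) {
        out(n, col) =
            scale * box_integral(xc[i], yc[j], zc, hx, hy, hz,
                                 electrodes(n, 0), electrodes(n, 1),
                                 electrodes(n, 2));
      }
    }
  }
  return out;
}
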