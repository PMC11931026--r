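// Brute-force ray/box oracle: dense marching along each ray with a fixed
// step, testing point-in-box containment.  Rays that pass within a few
// steps of the box without registering a hit are re-marched at a much finer
// step around the closest approach, so chords shorter than the coarse step
// are still detected.  Used only as an independent cross-check of the slab
// intersection rule in the test suite.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline bool in_box(double x, double y, double z,
                          const NumericVector& bmin,
                          const NumericVector& bmax) {
  return x >= bmin[0] && x <= bmax[0] && y >= bmin[1] && y <= bmax[1] &&
         z >= bmin[2] && z <= bmax[2];
}

static inline double box_dist(double x, double y, double z,
                              const NumericVector& bmin,
                              const NumericVector& bmax) {
  double dx = std::max({bmin[0] - x, 0.0, x - bmax[0]});
  double dy = std::max({bmin[1] - y, 0.0, y - bmax[1]});
  double dz = std::max({bmin[2] - z, 0.0, z - bmax[2]});
  return std::sqrt(dx * dx + dy * dy + dz * dz);
}

// [[Rcpp::export]]
List cpp_ray_march_oracle(NumericMatrix origins, NumericMatrix dirs,
                          NumericVector bmin, NumericVector bmax,
                          double step, double t_far) {
  int n = origins.nrow();
  LogicalVector hit(n);
  NumericVector t_exit(n);
  for (int i = 0; i < n; ++i) {
    double ox = origins(i, 0), oy = origins(i, 1), oz = origins(i, 2);
    double dx = dirs(i, 0), dy = dirs(i, 1), dz = dirs(i, 2);
    bool any_in = false;
    double last_in = NA_REAL;
    double best_d = std::numeric_limits<double>::infinity(), best_t = 0.0;
    for (double t = 0.5 * step; t <= t_far; t += step) {
      double x = ox + t * dx, y = oy + t * dy, z = oz + t * dz;
      if (in_box(x, y, z, bmin, bmax)) {
        any_in = true;
        last_in = t;
      } else {
        double d = box_dist(x, y, z, bmin, bmax);
        if (d < best_d) {
          best_d = d;
          best_t = t;
        }
      }
    }
    // near miss at the coarse step: refine around the closest approach
    if (!any_in && best_d < 5.0 * step) {
      double fine = step / 500.0;
      double lo = std::max(0.0, best_t - 2.0 * step);
      double hi = std::min(t_far, best_t + 2.0 * step);
      for (double t = lo; t <= hi; t += fine) {
        double x = ox + t * dx, y = oy + t * dy, z = oz + t * dz;
        if (in_box(x, y, z, bmin, bmax)) {
          any_in = true;
          last_in = t;
        }
      }
    }
    hit[i] = any_in;
    t_exit[i] = last_in;
  }
  return List::create(_["hit"] = hit, _["t_exit"] = t_exit);
}
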