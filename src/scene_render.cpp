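// Reference renderer for the synthetic scene: fixed-step quadrature of the
// emission-absorption volume-rendering integral against an analytic
// piecewise-constant density/color field.  Independent of the trained model.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Solid row layout (20 columns, 0-based):
//  0: type (0 = vertical cylinder, 1 = ellipsoid)
//  1-3: center (cylinder: cx, cy, unused)
//  4-6: cylinder: radius, z0, z1 / ellipsoid: semi-axes a, b, c
//  7-15: ellipsoid body-to-world rotation, row-major (unused for cylinder)
//  16-18: rgb color
//  19: density (1/m)
static inline bool solid_contains(const NumericMatrix& S, int i, double x,
                                  double y, double z) {
  if (S(i, 0) < 0.5) { // cylinder
    double dx = x - S(i, 1), dy = y - S(i, 2);
    return z >= S(i, 5) && z <= S(i, 6) &&
           dx * dx + dy * dy <= S(i, 4) * S(i, 4);
  }
  double dx = x - S(i, 1), dy = y - S(i, 2), dz = z - S(i, 3);
  // body coords u = Q^T (p - c); rotation stored row-major in cols 7..15
  double u0 = S(i, 7) * dx + S(i, 10) * dy + S(i, 13) * dz;
  double u1 = S(i, 8) * dx + S(i, 11) * dy + S(i, 14) * dz;
  double u2 = S(i, 9) * dx + S(i, 12) * dy + S(i, 15) * dz;
  double q = (u0 / S(i, 4)) * (u0 / S(i, 4)) + (u1 / S(i, 5)) * (u1 / S(i, 5)) +
             (u2 / S(i, 6)) * (u2 / S(i, 6));
  return q <= 1.0;
}

// density + color lookup; returns density, writes rgb (unmodulated)
static inline double field_eval(const NumericMatrix& solids,
                                const double* cyl, double x, double y,
                                double z, double* rgb) {
  rgb[0] = rgb[1] = rgb[2] = 0.5;
  // declared bounding cylinder: radius, z0, z1
  if (x * x + y * y > cyl[0] * cyl[0] || z < cyl[1] || z > cyl[2]) return 0.0;
  double best = 0.0;
  int n = solids.nrow();
  for (int i = 0; i < n; ++i) {
    if (solids(i, 19) > best && solid_contains(solids, i, x, y, z)) {
      best = solids(i, 19);
      rgb[0] = solids(i, 16); rgb[1] = solids(i, 17); rgb[2] = solids(i, 18);
    }
  }
  return best;
}

static inline double texture_mod(const double* tex, double x, double y,
                                 double z) {
  return 1.0 + tex[0] * std::sin(tex[1] * x) * std::sin(tex[1] * y) *
                   std::sin(tex[1] * z);
}

// [[Rcpp::export]]
NumericVector cpp_field_density(NumericMatrix solids, NumericVector cyl,
                                NumericMatrix pts) {
  int n = pts.nrow();
  NumericVector out(n);
  double rgb[3];
  for (int i = 0; i < n; ++i) {
    out[i] = field_eval(solids, &cyl[0], pts(i, 0), pts(i, 1), pts(i, 2), rgb);
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_field_color(NumericMatrix solids, NumericVector cyl,
                              NumericVector tex, NumericMatrix pts) {
  int n = pts.nrow();
  NumericMatrix out(n, 3);
  double rgb[3];
  for (int i = 0; i < n; ++i) {
    field_eval(solids, &cyl[0], pts(i, 0), pts(i, 1), pts(i, 2), rgb);
    double m = texture_mod(&tex[0], pts(i, 0), pts(i, 1), pts(i, 2));
    for (int c = 0; c < 3; ++c) {
      double v = rgb[c] * m;
      out(i, c) = v < 0.0 ? 0.0 : (v > 1.0 ? 1.0 : v);
    }
  }
  return out;
}

// Quadrature rendering: midpoint rule with n_quad fixed steps along each
// pixel ray over [0, t_far], composited onto a constant background.
// [[Rcpp::export]]
NumericVector cpp_render_gt(NumericMatrix solids, NumericVector cyl,
                            NumericVector tex, NumericVector bg,
                            NumericMatrix Rc2w, NumericVector center,
                            double fx, double fy, double cx, double cy,
                            int h, int w, int n_quad, double t_far) {
  NumericVector img(h * w * 3);
  img.attr("dim") = IntegerVector::create(h, w, 3);
  double dt = t_far / n_quad;
  double rgb[3];
  for (int col = 0; col < w; ++col) {
    for (int row = 0; row < h; ++row) {
      double xs = (col + 0.5 - cx) / fx;
      double ys = (row + 0.5 - cy) / fy;
      double nrm = std::sqrt(xs * xs + ys * ys + 1.0);
      double dc[3] = {xs / nrm, ys / nrm, 1.0 / nrm};
      double d[3];
      for (int k = 0; k < 3; ++k) {
        d[k] = Rc2w(k, 0) * dc[0] + Rc2w(k, 1) * dc[1] + Rc2w(k, 2) * dc[2];
      }
      double T = 1.0, acc[3] = {0.0, 0.0, 0.0};
      for (int q = 0; q < n_quad && T > 1e-7; ++q) {
        double t = (q + 0.5) * dt;
        double px = center[0] + t * d[0];
        double py = center[1] + t * d[1];
        double pz = center[2] + t * d[2];
        double sig = field_eval(solids, &cyl[0], px, py, pz, rgb);
        if (sig > 0.0) {
          double a = 1.0 - std::exp(-sig * dt);
          double m = texture_mod(&tex[0], px, py, pz);
          for (int c = 0; c < 3; ++c) {
            double v = rgb[c] * m;
            v = v < 0.0 ? 0.0 : (v > 1.0 ? 1.0 : v);
            acc[c] += T * a * v;
          }
          T *= 1.0 - a;
        }
      }
      for (int c = 0; c < 3; ++c) {
        img[row + h * (col + w * c)] = acc[c] + T * bg[c];
      }
    }
  }
  return img;
}

// Separable Gaussian blur with replicate border padding; kernel radius
// ceil(3*sigma).
// [[Rcpp::export]]
NumericVector cpp_gaussian_blur(NumericVector img, double sigma) {
  IntegerVector dim = img.attr("dim");
  int h = dim[0], w = dim[1], nc = dim.size() > 2 ? dim[2] : 1;
  int rad = (int)std::ceil(3.0 * sigma);
  std::vector<double> ker(2 * rad + 1);
  double s = 0.0;
  for (int i = -rad; i <= rad; ++i) {
    ker[i + rad] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += ker[i + rad];
  }
  for (auto& k : ker) k /= s;
  NumericVector out = clone(img);
  std::vector<double> tmp(h * w);
  for (int c = 0; c < nc; ++c) {
    double* ch = &out[(size_t)h * w * c];
    // vertical
    for (int x = 0; x < w; ++x) {
      for (int y = 0; y < h; ++y) {
        double acc = 0.0;
        for (int i = -rad; i <= rad; ++i) {
          int yy = y + i;
          yy = yy < 0 ? 0 : (yy >= h ? h - 1 : yy);
          acc += ker[i + rad] * ch[yy + h * x];
        }
        tmp[y + h * x] = acc;
      }
    }
    // horizontal
    for (int x = 0; x < w; ++x) {
      for (int y = 0; y < h; ++y) {
        double acc = 0.0;
        for (int i = -rad; i <= rad; ++i) {
          int xx = x + i;
          xx = xx < 0 ? 0 : (xx >= w ? w - 1 : xx);
          acc += ker[i + rad] * tmp[y + h * xx];
        }
        ch[y + h * x] = acc;
      }
    }
  }
  return out;
}
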