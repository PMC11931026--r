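// Radiance-field core: multi-resolution hash encoding, shallow density and
// color perceptrons, ROI-constrained hierarchical ray sampling, volume
// rendering, and analytic reverse-mode gradients (including per-image
// exposure and camera-pose offset parameters) with an Adam optimizer.
//
// Conventions: positions are normalized to the ROI box ([0,1]^3, clamped);
// sample batches are stored column-wise (one sample per column) so layer
// evaluations are single GEMMs.  Sample t-values are generated from the
// *base* (un-offset) poses and treated as constants in the backward pass;
// pose offsets act on the evaluation positions x = o(dt) + t * d(dtheta)
// and on the view direction only.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
#include <random>
using namespace Rcpp;

static const double LN2 = 0.6931471805599453;

// ---------------------------------------------------------------------------
// activations
static inline double softplus(double x) {
  return x > 30.0 ? x : std::log1p(std::exp(x));
}
static inline double logistic(double x) { return 1.0 / (1.0 + std::exp(-x)); }

static arma::mat relu(const arma::mat& x) { return arma::clamp(x, 0.0, arma::datum::inf); }

// ---------------------------------------------------------------------------
// multi-resolution hash grid
struct HashGrid {
  arma::mat tab;            // F x total entries
  std::vector<int> res;     // per-level grid resolution N_l (cells per axis)
  std::vector<long long> off; // per-level entry offsets (length L+1)
  int F, L;
};

static HashGrid grid_from_list(const List& params, const std::string& tab_name,
                               const std::string& res_name,
                               const std::string& off_name) {
  HashGrid g;
  g.tab = as<arma::mat>(params[tab_name]);
  IntegerVector r = params[res_name];
  NumericVector o = params[off_name];
  g.L = r.size();
  g.F = g.tab.n_rows;
  g.res.assign(r.begin(), r.end());
  g.off.resize(o.size());
  for (int i = 0; i < o.size(); ++i) g.off[i] = (long long)o[i];
  return g;
}

static inline long long corner_entry(const HashGrid& g, int l, long long ix,
                                     long long iy, long long iz) {
  long long n1 = (long long)g.res[l] + 1;
  long long m = g.off[l + 1] - g.off[l];
  if (n1 * n1 * n1 <= m) {
    return g.off[l] + ix + n1 * (iy + n1 * iz);
  }
  // Instant-NGP spatial hash; m is a power of two
  uint32_t h = (uint32_t)ix ^ ((uint32_t)iy * 2654435761u) ^
               ((uint32_t)iz * 805459861u);
  return g.off[l] + (long long)(h & (uint32_t)(m - 1));
}

// forward: P (3 x N, in [0,1]) -> feat (L*F x N)
static void hash_forward(const HashGrid& g, const arma::mat& P,
                         arma::mat& feat) {
  int N = P.n_cols;
  feat.set_size(g.L * g.F, N);
  for (int n = 0; n < N; ++n) {
    for (int l = 0; l < g.L; ++l) {
      int r = g.res[l];
      double u[3], fr[3];
      long long ii[3];
      for (int c = 0; c < 3; ++c) {
        u[c] = P(c, n) * r;
        long long i = (long long)std::floor(u[c]);
        if (i >= r) i = r - 1;
        if (i < 0) i = 0;
        ii[c] = i;
        fr[c] = u[c] - i;
        if (fr[c] > 1.0) fr[c] = 1.0;
      }
      double acc0 = 0.0, acc1 = 0.0;
      for (int cx = 0; cx < 2; ++cx) {
        double wx = cx ? fr[0] : 1.0 - fr[0];
        for (int cy = 0; cy < 2; ++cy) {
          double wy = cy ? fr[1] : 1.0 - fr[1];
          for (int cz = 0; cz < 2; ++cz) {
            double w = wx * wy * (cz ? fr[2] : 1.0 - fr[2]);
            long long e = corner_entry(g, l, ii[0] + cx, ii[1] + cy, ii[2] + cz);
            acc0 += w * g.tab(0, e);
            if (g.F > 1) acc1 += w * g.tab(1, e);
          }
        }
      }
      feat(l * g.F + 0, n) = acc0;
      if (g.F > 1) feat(l * g.F + 1, n) = acc1;
    }
  }
}

// backward: accumulates table gradients and (optionally) position gradients
// (in normalized coordinates)
static void hash_backward(const HashGrid& g, const arma::mat& P,
                          const arma::mat& dfeat, arma::mat& gtab,
                          arma::mat* dP) {
  int N = P.n_cols;
  for (int n = 0; n < N; ++n) {
    for (int l = 0; l < g.L; ++l) {
      int r = g.res[l];
      double u[3], fr[3];
      long long ii[3];
      for (int c = 0; c < 3; ++c) {
        u[c] = P(c, n) * r;
        long long i = (long long)std::floor(u[c]);
        if (i >= r) i = r - 1;
        if (i < 0) i = 0;
        ii[c] = i;
        fr[c] = u[c] - i;
        if (fr[c] > 1.0) fr[c] = 1.0;
      }
      double df0 = dfeat(l * g.F + 0, n);
      double df1 = g.F > 1 ? dfeat(l * g.F + 1, n) : 0.0;
      double gp[3] = {0.0, 0.0, 0.0};
      for (int cx = 0; cx < 2; ++cx) {
        double wx = cx ? fr[0] : 1.0 - fr[0];
        double sx = cx ? 1.0 : -1.0;
        for (int cy = 0; cy < 2; ++cy) {
          double wy = cy ? fr[1] : 1.0 - fr[1];
          double sy = cy ? 1.0 : -1.0;
          for (int cz = 0; cz < 2; ++cz) {
            double wz = cz ? fr[2] : 1.0 - fr[2];
            double sz = cz ? 1.0 : -1.0;
            long long e = corner_entry(g, l, ii[0] + cx, ii[1] + cy, ii[2] + cz);
            double w = wx * wy * wz;
            gtab(0, e) += w * df0;
            double fdot = g.tab(0, e) * df0;
            if (g.F > 1) {
              gtab(1, e) += w * df1;
              fdot += g.tab(1, e) * df1;
            }
            if (dP) {
              gp[0] += sx * wy * wz * fdot;
              gp[1] += wx * sy * wz * fdot;
              gp[2] += wx * wy * sz * fdot;
            }
          }
        }
      }
      if (dP) {
        for (int c = 0; c < 3; ++c) (*dP)(c, n) += gp[c] * r;
      }
    }
  }
}

// ---------------------------------------------------------------------------
// direction encoding: [d, sin(2^j pi d), cos(2^j pi d)] for j = 0..3 (27-dim)
static const int DIRENC_DIM = 27;
static void dir_encode(const double* d, double* out) {
  for (int c = 0; c < 3; ++c) out[c] = d[c];
  for (int j = 0; j < 4; ++j) {
    double f = std::pow(2.0, j) * M_PI;
    for (int c = 0; c < 3; ++c) {
      out[3 + 6 * j + c] = std::sin(f * d[c]);
      out[3 + 6 * j + 3 + c] = std::cos(f * d[c]);
    }
  }
}
static void dir_encode_backward(const double* d, const double* denc,
                                double* dd) {
  for (int c = 0; c < 3; ++c) dd[c] += denc[c];
  for (int j = 0; j < 4; ++j) {
    double f = std::pow(2.0, j) * M_PI;
    for (int c = 0; c < 3; ++c) {
      dd[c] += denc[3 + 6 * j + c] * f * std::cos(f * d[c]);
      dd[c] -= denc[3 + 6 * j + 3 + c] * f * std::sin(f * d[c]);
    }
  }
}

// ---------------------------------------------------------------------------
// rotation helpers
static arma::mat33 skew(const arma::vec3& v) {
  arma::mat33 K;
  K(0, 0) = 0;      K(0, 1) = -v(2); K(0, 2) = v(1);
  K(1, 0) = v(2);   K(1, 1) = 0;     K(1, 2) = -v(0);
  K(2, 0) = -v(1);  K(2, 1) = v(0);  K(2, 2) = 0;
  return K;
}
static arma::mat33 rot_exp(const arma::vec3& th) {
  double a = arma::norm(th);
  arma::mat33 I = arma::eye(3, 3);
  if (a < 1e-12) {
    arma::mat33 K = skew(th);
    return I + K + 0.5 * K * K;
  }
  arma::mat33 K = skew(th / a);
  return I + std::sin(a) * K + (1.0 - std::cos(a)) * (K * K);
}
// dW/dtheta_j contracted with a fixed vector v: returns d(W v)/dtheta (3x3,
// column j = partial wrt theta_j); Gallego & Yezzi closed form.
static arma::mat33 rot_exp_jacobian_times(const arma::vec3& th,
                                          const arma::mat33& W,
                                          const arma::vec3& v) {
  arma::mat33 J;
  double a2 = arma::dot(th, th);
  arma::vec3 Wv = W * v;
  if (a2 < 1e-16) {
    for (int j = 0; j < 3; ++j) {
      arma::vec3 e = arma::zeros<arma::vec>(3);
      e(j) = 1.0;
      J.col(j) = arma::cross(e, Wv);
    }
    return J;
  }
  arma::mat33 I = arma::eye(3, 3);
  for (int j = 0; j < 3; ++j) {
    arma::vec3 e = arma::zeros<arma::vec>(3);
    e(j) = 1.0;
    arma::vec3 w = th(j) * th + arma::cross(th, (I - W) * e);
    arma::mat33 dW = (skew(w) / a2) * W;
    J.col(j) = dW * v;
  }
  return J;
}

// ---------------------------------------------------------------------------
// parameters / gradients container
struct Params {
  HashGrid fg, cg;
  arma::mat W1, W2, V1, V2, V3, U1, U2;
  arma::vec b1, b2, c1, c2, c3, u1, u2;
  arma::vec E;
  arma::mat dT, dTh; // 3 x n_img
};

static Params params_from_list(const List& p) {
  Params P;
  P.fg = grid_from_list(p, "f_tab", "f_res", "f_off");
  P.cg = grid_from_list(p, "c_tab", "c_res", "c_off");
  P.W1 = as<arma::mat>(p["W1"]); P.b1 = as<arma::vec>(p["b1"]);
  P.W2 = as<arma::mat>(p["W2"]); P.b2 = as<arma::vec>(p["b2"]);
  P.V1 = as<arma::mat>(p["V1"]); P.c1 = as<arma::vec>(p["c1"]);
  P.V2 = as<arma::mat>(p["V2"]); P.c2 = as<arma::vec>(p["c2"]);
  P.V3 = as<arma::mat>(p["V3"]); P.c3 = as<arma::vec>(p["c3"]);
  P.U1 = as<arma::mat>(p["U1"]); P.u1 = as<arma::vec>(p["u1"]);
  P.U2 = as<arma::mat>(p["U2"]); P.u2 = as<arma::vec>(p["u2"]);
  P.E = as<arma::vec>(p["E"]);
  P.dT = as<arma::mat>(p["dT"]);
  P.dTh = as<arma::mat>(p["dTh"]);
  return P;
}

struct Grads {
  arma::mat ftab, ctab;
  arma::mat W1, W2, V1, V2, V3, U1, U2;
  arma::vec b1, b2, c1, c2, c3, u1, u2;
  arma::vec E;
  arma::mat dT, dTh;
  void init(const Params& P) {
    ftab.zeros(P.fg.tab.n_rows, P.fg.tab.n_cols);
    ctab.zeros(P.cg.tab.n_rows, P.cg.tab.n_cols);
    W1.zeros(arma::size(P.W1)); b1.zeros(arma::size(P.b1));
    W2.zeros(arma::size(P.W2)); b2.zeros(arma::size(P.b2));
    V1.zeros(arma::size(P.V1)); c1.zeros(arma::size(P.c1));
    V2.zeros(arma::size(P.V2)); c2.zeros(arma::size(P.c2));
    V3.zeros(arma::size(P.V3)); c3.zeros(arma::size(P.c3));
    U1.zeros(arma::size(P.U1)); u1.zeros(arma::size(P.u1));
    U2.zeros(arma::size(P.U2)); u2.zeros(arma::size(P.u2));
    E.zeros(arma::size(P.E));
    dT.zeros(arma::size(P.dT)); dTh.zeros(arma::size(P.dTh));
  }
};

struct Config {
  arma::vec3 amin, amax, bg;
  int n_c, n_f;
  double roi_frac, t_b, lambda_E, lambda_p;
};

static Config config_from_list(const List& cfg) {
  Config C;
  C.amin = as<arma::vec>(cfg["aabb_min"]);
  C.amax = as<arma::vec>(cfg["aabb_max"]);
  C.bg = as<arma::vec>(cfg["bg"]);
  C.n_c = as<int>(cfg["n_c"]);
  C.n_f = as<int>(cfg["n_f"]);
  C.roi_frac = as<double>(cfg["roi_frac"]);
  C.t_b = as<double>(cfg["t_b"]);
  C.lambda_E = as<double>(cfg["lambda_E"]);
  C.lambda_p = as<double>(cfg["lambda_p"]);
  return C;
}

// ---------------------------------------------------------------------------
// geometry: slab intersection with the ROI box (t_min clamped to 0)
static bool slab_tmax(const Config& C, const double* o, const double* d,
                      double& t_exit) {
  double t0 = -std::numeric_limits<double>::infinity();
  double t1 = std::numeric_limits<double>::infinity();
  for (int c = 0; c < 3; ++c) {
    if (std::abs(d[c]) < 1e-14) {
      if (o[c] < C.amin(c) || o[c] > C.amax(c)) return false;
      continue;
    }
    double a = (C.amin(c) - o[c]) / d[c];
    double b = (C.amax(c) - o[c]) / d[c];
    if (a > b) std::swap(a, b);
    if (a > t0) t0 = a;
    if (b < t1) t1 = b;
  }
  if (t0 > t1 || t1 < 0.0) return false;
  t_exit = t1;
  return true;
}

// stratified two-region coarse samples along (0, t_b]
static void coarse_samples(const Config& C, bool hit, double t_exit,
                           std::mt19937_64* rng, double* t) {
  std::uniform_real_distribution<double> U(0.0, 1.0);
  int n1 = hit ? (int)std::lround(C.roi_frac * C.n_c) : C.n_c;
  if (hit) {
    if (n1 < 1) n1 = 1;
    if (n1 > C.n_c - 1) n1 = C.n_c - 1;
    if (t_exit <= 1e-9) n1 = 1;
  }
  double edge = hit ? std::min(t_exit, C.t_b) : C.t_b;
  int n2 = C.n_c - n1;
  for (int i = 0; i < n1; ++i) {
    double u = rng ? U(*rng) : 0.5;
    t[i] = (i + u) / n1 * edge;
  }
  for (int i = 0; i < n2; ++i) {
    double u = rng ? U(*rng) : 0.5;
    t[n1 + i] = edge + (i + u) / n2 * (C.t_b - edge);
  }
}

// inverse-transform sampling of n_f points from the piecewise-constant pdf
// over the coarse bins [t_k, t_{k+1}) (last bin ends at t_b); output sorted
static void fine_samples(const double* tc, int nc, double t_b,
                         const double* w, int nf, std::mt19937_64* rng,
                         double* out) {
  std::vector<double> prob(nc);
  double s = 0.0;
  for (int k = 0; k < nc; ++k) s += w[k];
  if (s <= 1e-12) {
    for (int k = 0; k < nc; ++k) prob[k] = 1.0 / nc;
  } else {
    for (int k = 0; k < nc; ++k) prob[k] = w[k] / s;
  }
  std::vector<double> cdf(nc);
  double acc = 0.0;
  for (int k = 0; k < nc; ++k) { acc += prob[k]; cdf[k] = acc; }
  cdf[nc - 1] = 1.0;
  std::uniform_real_distribution<double> U(0.0, 1.0);
  for (int j = 0; j < nf; ++j) {
    double u = rng ? U(*rng) : (j + 0.5) / nf;
    int k = (int)(std::lower_bound(cdf.begin(), cdf.end(), u) - cdf.begin());
    if (k >= nc) k = nc - 1;
    double clo = k == 0 ? 0.0 : cdf[k - 1];
    double frac = prob[k] > 1e-300 ? (u - clo) / prob[k] : 0.5;
    if (frac < 0.0) frac = 0.0;
    if (frac > 1.0) frac = 1.0;
    double blo = tc[k];
    double bhi = k + 1 < nc ? tc[k + 1] : t_b;
    out[j] = blo + frac * (bhi - blo);
  }
  if (rng) std::sort(out, out + nf);
}

// emission-absorption compositing; caches T_k and alpha_k for the backward
static void composite_fwd(const double* t, int n, double t_b,
                          const double* sigma, const arma::mat& rgb, int off,
                          const arma::vec3& bg, double* C, double* Tk,
                          double* alpha, double& Tres) {
  double T = 1.0;
  C[0] = C[1] = C[2] = 0.0;
  for (int k = 0; k < n; ++k) {
    double dlt = (k + 1 < n ? t[k + 1] : t_b) - t[k];
    if (dlt < 0.0) dlt = 0.0;
    double a = 1.0 - std::exp(-sigma[k] * dlt);
    Tk[k] = T;
    alpha[k] = a;
    double w = T * a;
    for (int c = 0; c < 3; ++c) C[c] += w * rgb(c, off + k);
    T *= 1.0 - a;
  }
  Tres = T;
  for (int c = 0; c < 3; ++c) C[c] += T * bg(c);
}

static void composite_bwd(const double* t, int n, double t_b,
                          const arma::mat& rgb, int off, const arma::vec3& bg,
                          const double* Tk, const double* alpha, double Tres,
                          const double* dC, double* dsigma, arma::mat& drgb) {
  double suffix[3] = {Tres * bg(0), Tres * bg(1), Tres * bg(2)};
  for (int k = n - 1; k >= 0; --k) {
    double dlt = (k + 1 < n ? t[k + 1] : t_b) - t[k];
    if (dlt < 0.0) dlt = 0.0;
    double w = Tk[k] * alpha[k];
    double Tk1 = Tk[k] * (1.0 - alpha[k]);
    double ds = 0.0;
    for (int c = 0; c < 3; ++c) {
      ds += dC[c] * (Tk1 * rgb(c, off + k) - suffix[c]);
      drgb(c, off + k) += w * dC[c];
      suffix[c] += w * rgb(c, off + k);
    }
    dsigma[k] = ds * dlt;
  }
}

// normalize world positions to the ROI box; mask = 1 where unclamped
static void normalize_pos(const Config& C, const arma::mat& Pw, arma::mat& Pn,
                          arma::mat& mask) {
  int N = Pw.n_cols;
  Pn.set_size(3, N);
  mask.set_size(3, N);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < 3; ++c) {
      double v = (Pw(c, n) - C.amin(c)) / (C.amax(c) - C.amin(c));
      if (v <= 0.0) { Pn(c, n) = 0.0; mask(c, n) = 0.0; }
      else if (v >= 1.0) { Pn(c, n) = 1.0; mask(c, n) = 0.0; }
      else { Pn(c, n) = v; mask(c, n) = 1.0; }
    }
  }
}

// ---------------------------------------------------------------------------
// batch forward/backward
struct RayBatch {
  int B;
  std::vector<int> img;   // 0-based image index (or -1: no exposure/offsets)
  arma::mat obs;          // 3 x B (ignored if img[.] < 0 and no grads)
  arma::mat o0, d0;       // base origins / unit directions, 3 x B
};

// Full forward (and optionally backward) pass for one ray batch.  Returns the
// fine-pass colors in Cf (3 x B) and, when G != NULL, accumulates parameter
// gradients of the photometric loss
//   (1/(3B)) sum_rays |S_i Cf - obs|^2 + |S_i Cc - obs|^2 .
static double run_batch(const Params& P, Grads* G, const Config& C,
                        const RayBatch& rb, std::mt19937_64* rng,
                        arma::mat& Cf_out) {
  const int B = rb.B, Nc = C.n_c, Nf = C.n_f, Nt = Nc + Nf;
  arma::mat tc(Nc, B), tf(Nt, B);
  arma::mat o(3, B), d(3, B);       // offset-applied origin / direction
  std::vector<arma::mat33> Wth(B);  // offset rotations per ray

  for (int r = 0; r < B; ++r) {
    arma::vec3 oo = rb.o0.col(r), dd = rb.d0.col(r);
    int i = rb.img[r];
    if (i >= 0) {
      arma::vec3 th = P.dTh.col(i);
      Wth[r] = rot_exp(th);
      dd = Wth[r] * dd;
      oo += P.dT.col(i);
    } else {
      Wth[r] = arma::eye(3, 3);
    }
    o.col(r) = oo;
    d.col(r) = dd;
    double t_exit;
    bool hit = slab_tmax(C, rb.o0.colptr(r), rb.d0.colptr(r), t_exit);
    coarse_samples(C, hit, hit ? t_exit : 0.0, rng, tc.colptr(r));
  }

  // ---- coarse pass (base poses: the coarse stage is a sampling guide and
  // its own photometric loss; pose offsets act only on the fine pass, so
  // sample placement is independent of the offset parameters) ----
  arma::mat Pc(3, B * Nc);
  for (int r = 0; r < B; ++r) {
    for (int k = 0; k < Nc; ++k) {
      Pc.col(r * Nc + k) = rb.o0.col(r) + tc(k, r) * rb.d0.col(r);
    }
  }
  arma::mat Pcn, McM;
  normalize_pos(C, Pc, Pcn, McM);
  arma::mat Xc;
  hash_forward(P.cg, Pcn, Xc);
  arma::mat Hc_pre = P.U1 * Xc;
  Hc_pre.each_col() += P.u1;
  arma::mat Hc = relu(Hc_pre);
  arma::mat Oc = P.U2 * Hc;
  Oc.each_col() += P.u2;
  arma::vec sig_c(B * Nc);
  arma::mat rgb_c(3, B * Nc);
  for (arma::uword n = 0; n < Oc.n_cols; ++n) {
    sig_c(n) = softplus(Oc(0, n));
    for (int c = 0; c < 3; ++c) rgb_c(c, n) = logistic(Oc(1 + c, n));
  }
  arma::mat Cc(3, B);
  arma::mat Tk_c(Nc, B), al_c(Nc, B);
  arma::vec Tres_c(B);
  arma::mat wts(Nc, B);
  for (int r = 0; r < B; ++r) {
    double Ccol[3], Tres;
    composite_fwd(tc.colptr(r), Nc, C.t_b, sig_c.memptr() + r * Nc, rgb_c,
                  r * Nc, C.bg, Ccol, Tk_c.colptr(r), al_c.colptr(r), Tres);
    Tres_c(r) = Tres;
    for (int c = 0; c < 3; ++c) Cc(c, r) = Ccol[c];
    for (int k = 0; k < Nc; ++k) wts(k, r) = Tk_c(k, r) * al_c(k, r);
  }

  // ---- fine sample locations ----
  for (int r = 0; r < B; ++r) {
    std::vector<double> ft(Nf);
    fine_samples(tc.colptr(r), Nc, C.t_b, wts.colptr(r), Nf, rng, ft.data());
    std::merge(tc.colptr(r), tc.colptr(r) + Nc, ft.begin(), ft.end(),
               tf.colptr(r));
  }

  // ---- fine pass ----
  arma::mat Pf(3, B * Nt);
  for (int r = 0; r < B; ++r) {
    for (int k = 0; k < Nt; ++k) {
      Pf.col(r * Nt + k) = o.col(r) + tf(k, r) * d.col(r);
    }
  }
  arma::mat Pfn, MfM;
  normalize_pos(C, Pf, Pfn, MfM);
  arma::mat Xf;
  hash_forward(P.fg, Pfn, Xf);
  arma::mat A1_pre = P.W1 * Xf;
  A1_pre.each_col() += P.b1;
  arma::mat A1 = relu(A1_pre);
  arma::mat Y = P.W2 * A1;
  Y.each_col() += P.b2;
  const int NG = Y.n_rows; // 16: raw density + 15 geometric features
  arma::vec sig_f(B * Nt);
  arma::mat Z(NG + DIRENC_DIM, B * Nt);
  arma::mat Denc(DIRENC_DIM, B);
  for (int r = 0; r < B; ++r) {
    double enc[DIRENC_DIM];
    dir_encode(d.colptr(r), enc);
    for (int c = 0; c < DIRENC_DIM; ++c) Denc(c, r) = enc[c];
  }
  for (int r = 0; r < B; ++r) {
    for (int k = 0; k < Nt; ++k) {
      arma::uword n = r * Nt + k;
      sig_f(n) = softplus(Y(0, n));
      Z(0, n) = Y(0, n); // raw density value is the 16th geometric component
      for (int j = 1; j < NG; ++j) {
        double y = Y(j, n);
        Z(j, n) = y > 0.0 ? y : std::expm1(y); // ELU
      }
      for (int c = 0; c < DIRENC_DIM; ++c) Z(NG + c, n) = Denc(c, r);
    }
  }
  arma::mat B1_pre = P.V1 * Z;
  B1_pre.each_col() += P.c1;
  arma::mat B1 = relu(B1_pre);
  arma::mat B2_pre = P.V2 * B1;
  B2_pre.each_col() += P.c2;
  arma::mat B2 = relu(B2_pre);
  arma::mat O3 = P.V3 * B2;
  O3.each_col() += P.c3;
  arma::mat rgb_f(3, B * Nt);
  for (arma::uword n = 0; n < O3.n_cols; ++n) {
    for (int c = 0; c < 3; ++c) rgb_f(c, n) = logistic(O3(c, n));
  }
  arma::mat Cf(3, B);
  arma::mat Tk_f(Nt, B), al_f(Nt, B);
  arma::vec Tres_f(B);
  for (int r = 0; r < B; ++r) {
    double Ccol[3], Tres;
    composite_fwd(tf.colptr(r), Nt, C.t_b, sig_f.memptr() + r * Nt, rgb_f,
                  r * Nt, C.bg, Ccol, Tk_f.colptr(r), al_f.colptr(r), Tres);
    Tres_f(r) = Tres;
    for (int c = 0; c < 3; ++c) Cf(c, r) = Ccol[c];
  }
  Cf_out = Cf;

  // ---- loss ----
  double loss = 0.0;
  arma::vec S(B);
  for (int r = 0; r < B; ++r) {
    int i = rb.img[r];
    S(r) = i >= 0 ? std::exp(LN2 * P.E(i)) : 1.0;
    for (int c = 0; c < 3; ++c) {
      double rf = S(r) * Cf(c, r) - rb.obs(c, r);
      double rc = S(r) * Cc(c, r) - rb.obs(c, r);
      loss += rf * rf + rc * rc;
    }
  }
  loss /= 3.0 * B;
  if (!G) return loss;

  // ---- backward ----
  const double sc = 2.0 / (3.0 * B);
  arma::mat dsig_f(Nt, B, arma::fill::zeros), drgb_f(3, B * Nt,
                                                     arma::fill::zeros);
  arma::mat dsig_c(Nc, B, arma::fill::zeros), drgb_c(3, B * Nc,
                                                     arma::fill::zeros);
  for (int r = 0; r < B; ++r) {
    int i = rb.img[r];
    double dCf[3], dCc[3];
    for (int c = 0; c < 3; ++c) {
      double rf = S(r) * Cf(c, r) - rb.obs(c, r);
      double rc = S(r) * Cc(c, r) - rb.obs(c, r);
      dCf[c] = sc * S(r) * rf;
      dCc[c] = sc * S(r) * rc;
      if (i >= 0) {
        G->E(i) += sc * LN2 * S(r) * (rf * Cf(c, r) + rc * Cc(c, r));
      }
    }
    composite_bwd(tf.colptr(r), Nt, C.t_b, rgb_f, r * Nt, C.bg,
                  Tk_f.colptr(r), al_f.colptr(r), Tres_f(r), dCf,
                  dsig_f.colptr(r), drgb_f);
    composite_bwd(tc.colptr(r), Nc, C.t_b, rgb_c, r * Nc, C.bg,
                  Tk_c.colptr(r), al_c.colptr(r), Tres_c(r), dCc,
                  dsig_c.colptr(r), drgb_c);
  }

  // fine color net backward
  arma::mat dO3(3, B * Nt);
  for (arma::uword n = 0; n < dO3.n_cols; ++n) {
    for (int c = 0; c < 3; ++c) {
      dO3(c, n) = drgb_f(c, n) * rgb_f(c, n) * (1.0 - rgb_f(c, n));
    }
  }
  G->V3 += dO3 * B2.t();
  G->c3 += arma::sum(dO3, 1);
  arma::mat dB2 = (P.V3.t() * dO3) % arma::conv_to<arma::mat>::from(B2_pre > 0.0);
  G->V2 += dB2 * B1.t();
  G->c2 += arma::sum(dB2, 1);
  arma::mat dB1 = (P.V2.t() * dB2) % arma::conv_to<arma::mat>::from(B1_pre > 0.0);
  G->V1 += dB1 * Z.t();
  G->c1 += arma::sum(dB1, 1);
  arma::mat dZ = P.V1.t() * dB1;

  // fine density net backward (raw density feeds both softplus and geo16[0])
  arma::mat dY(NG, B * Nt);
  for (int r = 0; r < B; ++r) {
    for (int k = 0; k < Nt; ++k) {
      arma::uword n = r * Nt + k;
      dY(0, n) = dsig_f(k, r) * logistic(Y(0, n)) + dZ(0, n);
      for (int j = 1; j < NG; ++j) {
        double y = Y(j, n);
        dY(j, n) = dZ(j, n) * (y > 0.0 ? 1.0 : std::exp(y));
      }
    }
  }
  G->W2 += dY * A1.t();
  G->b2 += arma::sum(dY, 1);
  arma::mat dA1 = (P.W2.t() * dY) % arma::conv_to<arma::mat>::from(A1_pre > 0.0);
  G->W1 += dA1 * Xf.t();
  G->b1 += arma::sum(dA1, 1);
  arma::mat dXf = P.W1.t() * dA1;
  arma::mat dPfn(3, B * Nt, arma::fill::zeros);
  hash_backward(P.fg, Pfn, dXf, G->ftab, &dPfn);

  // coarse net backward
  arma::mat dOc(4, B * Nc);
  for (int r = 0; r < B; ++r) {
    for (int k = 0; k < Nc; ++k) {
      arma::uword n = r * Nc + k;
      dOc(0, n) = dsig_c(k, r) * logistic(Oc(0, n));
      for (int c = 0; c < 3; ++c) {
        dOc(1 + c, n) = drgb_c(c, n) * rgb_c(c, n) * (1.0 - rgb_c(c, n));
      }
    }
  }
  G->U2 += dOc * Hc.t();
  G->u2 += arma::sum(dOc, 1);
  arma::mat dHc = (P.U2.t() * dOc) % arma::conv_to<arma::mat>::from(Hc_pre > 0.0);
  G->U1 += dHc * Xc.t();
  G->u1 += arma::sum(dHc, 1);
  arma::mat dXc = P.U1.t() * dHc;
  arma::mat dPcn(3, B * Nc, arma::fill::zeros);
  hash_backward(P.cg, Pcn, dXc, G->ctab, &dPcn);

  // pose-offset gradients: world-position grads + view-direction grads
  bool any_pose = false;
  for (int r = 0; r < B; ++r) if (rb.img[r] >= 0) { any_pose = true; break; }
  if (any_pose) {
    arma::mat dDenc_r(DIRENC_DIM, B, arma::fill::zeros);
    for (int r = 0; r < B; ++r) {
      for (int k = 0; k < Nt; ++k) {
        for (int c = 0; c < DIRENC_DIM; ++c) {
          dDenc_r(c, r) += dZ(NG + c, r * Nt + k);
        }
      }
    }
    for (int r = 0; r < B; ++r) {
      int i = rb.img[r];
      if (i < 0) continue;
      arma::vec3 dOr = arma::zeros<arma::vec>(3);
      arma::vec3 dDr = arma::zeros<arma::vec>(3);
      for (int k = 0; k < Nt; ++k) {
        arma::uword n = r * Nt + k;
        for (int c = 0; c < 3; ++c) {
          double g = dPfn(c, n) * MfM(c, n) / (C.amax(c) - C.amin(c));
          dOr(c) += g;
          dDr(c) += g * tf(k, r);
        }
      }
      double ddir[3] = {dDr(0), dDr(1), dDr(2)};
      dir_encode_backward(d.colptr(r), dDenc_r.colptr(r), ddir);
      arma::vec3 dDfull = {ddir[0], ddir[1], ddir[2]};
      G->dT.col(i) += dOr;
      arma::vec3 th = P.dTh.col(i);
      arma::mat33 J = rot_exp_jacobian_times(th, Wth[r], rb.d0.col(r));
      G->dTh.col(i) += J.t() * dDfull;
    }
  }
  return loss;
}

// regularizers: lambda_E * sum E^2 + lambda_p * sum(|dT|^2 + |dTh|^2)
static double reg_loss_grads(const Params& P, Grads* G, const Config& C) {
  double l = C.lambda_E * arma::dot(P.E, P.E) +
             C.lambda_p * (arma::accu(P.dT % P.dT) + arma::accu(P.dTh % P.dTh));
  if (G) {
    G->E += 2.0 * C.lambda_E * P.E;
    G->dT += 2.0 * C.lambda_p * P.dT;
    G->dTh += 2.0 * C.lambda_p * P.dTh;
  }
  return l;
}

// ---------------------------------------------------------------------------
// ray construction from images / intrinsics
struct Capture {
  const double* images; // H x W x 3 x n
  int H, W, n;
  arma::cube Rc2w;      // 3 x 3 x n
  arma::mat centers;    // 3 x n
  double fx, fy, cx, cy;
};

static void make_ray(const Capture& cap, int img, int row, int col,
                     arma::vec3& o, arma::vec3& d, arma::vec3& obs) {
  double xs = (col + 0.5 - cap.cx) / cap.fx;
  double ys = (row + 0.5 - cap.cy) / cap.fy;
  double nr = std::sqrt(xs * xs + ys * ys + 1.0);
  arma::vec3 dc = {xs / nr, ys / nr, 1.0 / nr};
  d = cap.Rc2w.slice(img) * dc;
  o = cap.centers.col(img);
  size_t base = (size_t)row + cap.H * ((size_t)col);
  size_t stride = (size_t)cap.H * cap.W;
  for (int c = 0; c < 3; ++c) {
    obs(c) = cap.images[base + stride * (c + 3 * (size_t)img)];
  }
}

static Capture capture_from_args(const NumericVector& images,
                                 const NumericVector& Rc2w,
                                 const NumericMatrix& centers,
                                 const NumericVector& intr) {
  Capture cap;
  IntegerVector dim = images.attr("dim");
  cap.H = dim[0]; cap.W = dim[1]; cap.n = dim[3];
  cap.images = &images[0];
  cap.Rc2w = arma::cube(&Rc2w[0], 3, 3, cap.n);
  cap.centers = as<arma::mat>(wrap(centers));
  cap.fx = intr[0]; cap.fy = intr[1]; cap.cx = intr[2]; cap.cy = intr[3];
  return cap;
}

// ---------------------------------------------------------------------------
// Adam
struct Adam {
  arma::mat m, v;
  void init(const arma::mat& p) { m.zeros(arma::size(p)); v.zeros(arma::size(p)); }
  void step(arma::mat& p, const arma::mat& g, double lr, int t) {
    m = 0.9 * m + 0.1 * g;
    v = 0.99 * v + 0.01 * (g % g);
    double bc1 = 1.0 - std::pow(0.9, t);
    double bc2 = 1.0 - std::pow(0.99, t);
    p -= lr * (m / bc1) / (arma::sqrt(v / bc2) + 1e-8);
  }
};
struct AdamV {
  arma::vec m, v;
  void init(const arma::vec& p) { m.zeros(arma::size(p)); v.zeros(arma::size(p)); }
  void step(arma::vec& p, const arma::vec& g, double lr, int t) {
    m = 0.9 * m + 0.1 * g;
    v = 0.99 * v + 0.01 * (g % g);
    double bc1 = 1.0 - std::pow(0.9, t);
    double bc2 = 1.0 - std::pow(0.99, t);
    p -= lr * (m / bc1) / (arma::sqrt(v / bc2) + 1e-8);
  }
};

static List params_to_list(const Params& P, const List& templ) {
  List out = clone(templ);
  out["f_tab"] = wrap(P.fg.tab);
  out["c_tab"] = wrap(P.cg.tab);
  out["W1"] = wrap(P.W1); out["b1"] = wrap(P.b1);
  out["W2"] = wrap(P.W2); out["b2"] = wrap(P.b2);
  out["V1"] = wrap(P.V1); out["c1"] = wrap(P.c1);
  out["V2"] = wrap(P.V2); out["c2"] = wrap(P.c2);
  out["V3"] = wrap(P.V3); out["c3"] = wrap(P.c3);
  out["U1"] = wrap(P.U1); out["u1"] = wrap(P.u1);
  out["U2"] = wrap(P.U2); out["u2"] = wrap(P.u2);
  out["E"] = wrap(P.E);
  out["dT"] = wrap(P.dT);
  out["dTh"] = wrap(P.dTh);
  return out;
}

// ---------------------------------------------------------------------------
// exported entry points

// [[Rcpp::export]]
NumericMatrix cpp_hash_encode(NumericMatrix tab, IntegerVector res,
                              NumericVector off, NumericMatrix pts) {
  HashGrid g;
  g.tab = as<arma::mat>(wrap(tab));
  g.F = g.tab.n_rows;
  g.L = res.size();
  g.res.assign(res.begin(), res.end());
  g.off.resize(off.size());
  for (int i = 0; i < off.size(); ++i) g.off[i] = (long long)off[i];
  arma::mat P(3, pts.nrow());
  for (int n = 0; n < pts.nrow(); ++n) {
    for (int c = 0; c < 3; ++c) {
      double v = pts(n, c);
      P(c, n) = v < 0.0 ? 0.0 : (v > 1.0 ? 1.0 : v);
    }
  }
  arma::mat feat;
  hash_forward(g, P, feat);
  return wrap(arma::mat(feat.t()));
}

// [[Rcpp::export]]
NumericVector cpp_query_density(List params, List cfg, NumericMatrix pts) {
  Params P = params_from_list(params);
  Config C = config_from_list(cfg);
  int N = pts.nrow();
  arma::mat Pw(3, N);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < 3; ++c) Pw(c, n) = pts(n, c);
  }
  arma::mat Pn, M;
  normalize_pos(C, Pw, Pn, M);
  NumericVector out(N);
  const int chunk = 65536;
  for (int s = 0; s < N; s += chunk) {
    int e = std::min(N, s + chunk);
    arma::mat X;
    hash_forward(P.fg, Pn.cols(s, e - 1), X);
    arma::mat A1 = P.W1 * X;
    A1.each_col() += P.b1;
    A1 = relu(A1);
    arma::rowvec y0 = P.W2.row(0) * A1 + P.b2(0);
    for (int n = s; n < e; ++n) out[n] = softplus(y0(n - s));
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_query_color(List params, List cfg, NumericMatrix pts,
                              NumericMatrix dirs) {
  Params P = params_from_list(params);
  Config C = config_from_list(cfg);
  int N = pts.nrow();
  arma::mat Pw(3, N), D(3, N);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < 3; ++c) {
      Pw(c, n) = pts(n, c);
      D(c, n) = dirs(n, c);
    }
  }
  arma::mat Pn, M;
  normalize_pos(C, Pw, Pn, M);
  arma::mat X;
  hash_forward(P.fg, Pn, X);
  arma::mat A1 = P.W1 * X;
  A1.each_col() += P.b1;
  A1 = relu(A1);
  arma::mat Y = P.W2 * A1;
  Y.each_col() += P.b2;
  const int NG = Y.n_rows;
  arma::mat Z(NG + DIRENC_DIM, N);
  for (int n = 0; n < N; ++n) {
    Z(0, n) = Y(0, n);
    for (int j = 1; j < NG; ++j) {
      double y = Y(j, n);
      Z(j, n) = y > 0.0 ? y : std::expm1(y);
    }
    double enc[DIRENC_DIM];
    double dv[3] = {D(0, n), D(1, n), D(2, n)};
    dir_encode(dv, enc);
    for (int c = 0; c < DIRENC_DIM; ++c) Z(NG + c, n) = enc[c];
  }
  arma::mat B1 = P.V1 * Z;
  B1.each_col() += P.c1;
  B1 = relu(B1);
  arma::mat B2 = P.V2 * B1;
  B2.each_col() += P.c2;
  B2 = relu(B2);
  arma::mat O3 = P.V3 * B2;
  O3.each_col() += P.c3;
  NumericMatrix out(N, 3);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < 3; ++c) out(n, c) = logistic(O3(c, n));
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_render_rays(List params, List cfg, NumericMatrix origins,
                              NumericMatrix dirs, bool jitter, int seed) {
  Params P = params_from_list(params);
  Config C = config_from_list(cfg);
  int N = origins.nrow();
  RayBatch rb;
  rb.B = N;
  rb.img.assign(N, -1);
  rb.obs.zeros(3, N);
  rb.o0.set_size(3, N);
  rb.d0.set_size(3, N);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < 3; ++c) {
      rb.o0(c, n) = origins(n, c);
      rb.d0(c, n) = dirs(n, c);
    }
  }
  std::mt19937_64 rng(seed);
  arma::mat Cf;
  run_batch(P, nullptr, C, rb, jitter ? &rng : nullptr, Cf);
  return wrap(arma::mat(Cf.t()));
}

// [[Rcpp::export]]
List cpp_loss_grads(List params, List cfg, NumericVector images,
                    NumericVector Rc2w, NumericMatrix centers,
                    NumericVector intr, IntegerVector img_id,
                    IntegerVector rows, IntegerVector cols, bool jitter,
                    int seed) {
  Params P = params_from_list(params);
  Config C = config_from_list(cfg);
  Capture cap = capture_from_args(images, Rc2w, centers, intr);
  int B = img_id.size();
  RayBatch rb;
  rb.B = B;
  rb.img.resize(B);
  rb.obs.set_size(3, B);
  rb.o0.set_size(3, B);
  rb.d0.set_size(3, B);
  for (int r = 0; r < B; ++r) {
    rb.img[r] = img_id[r] - 1;
    arma::vec3 o, d, obs;
    make_ray(cap, rb.img[r], rows[r] - 1, cols[r] - 1, o, d, obs);
    rb.o0.col(r) = o;
    rb.d0.col(r) = d;
    rb.obs.col(r) = obs;
  }
  Grads G;
  G.init(P);
  std::mt19937_64 rng(seed);
  arma::mat Cf;
  double loss = run_batch(P, &G, C, rb, jitter ? &rng : nullptr, Cf);
  loss += reg_loss_grads(P, &G, C);
  return List::create(_["loss"] = loss, _["gE"] = wrap(G.E),
                      _["gdT"] = wrap(G.dT), _["gdTh"] = wrap(G.dTh));
}

// [[Rcpp::export]]
List cpp_train(List params, List cfg, NumericVector images, NumericVector Rc2w,
               NumericMatrix centers, NumericVector intr, int n_iter,
               int batch, int seed, double lr_hash, double lr_mlp,
               double lr_E, double lr_pose, bool opt_exposure, bool opt_pose,
               int log_every) {
  Params P = params_from_list(params);
  Config C = config_from_list(cfg);
  Capture cap = capture_from_args(images, Rc2w, centers, intr);
  std::mt19937_64 rng((uint64_t)seed * 2654435761u + 1);
  std::uniform_int_distribution<int> Uimg(0, cap.n - 1), Urow(0, cap.H - 1),
      Ucol(0, cap.W - 1);

  Adam a_ftab, a_W1, a_W2, a_V1, a_V2, a_V3, a_ctab, a_U1, a_U2, a_dT, a_dTh;
  AdamV a_b1, a_b2, a_c1, a_c2, a_c3, a_u1, a_u2, a_E;
  a_ftab.init(P.fg.tab); a_ctab.init(P.cg.tab);
  a_W1.init(P.W1); a_W2.init(P.W2);
  a_V1.init(P.V1); a_V2.init(P.V2); a_V3.init(P.V3);
  a_U1.init(P.U1); a_U2.init(P.U2);
  a_dT.init(P.dT); a_dTh.init(P.dTh);
  a_b1.init(P.b1); a_b2.init(P.b2);
  a_c1.init(P.c1); a_c2.init(P.c2); a_c3.init(P.c3);
  a_u1.init(P.u1); a_u2.init(P.u2);
  a_E.init(P.E);

  std::vector<double> log_iter, log_loss;
  RayBatch rb;
  rb.B = batch;
  rb.img.resize(batch);
  rb.obs.set_size(3, batch);
  rb.o0.set_size(3, batch);
  rb.d0.set_size(3, batch);
  Grads G;
  for (int it = 1; it <= n_iter; ++it) {
    for (int r = 0; r < batch; ++r) {
      int i = Uimg(rng);
      int row = Urow(rng), col = Ucol(rng);
      rb.img[r] = i;
      arma::vec3 o, d, obs;
      make_ray(cap, i, row, col, o, d, obs);
      rb.o0.col(r) = o;
      rb.d0.col(r) = d;
      rb.obs.col(r) = obs;
    }
    G.init(P);
    arma::mat Cf;
    double loss = run_batch(P, &G, C, rb, &rng, Cf);
    loss += reg_loss_grads(P, &G, C);
    if (!std::isfinite(loss)) {
      stop("non-finite training loss at iteration %d", it);
    }
    a_ftab.step(P.fg.tab, G.ftab, lr_hash, it);
    a_ctab.step(P.cg.tab, G.ctab, lr_hash, it);
    a_W1.step(P.W1, G.W1, lr_mlp, it); a_b1.step(P.b1, G.b1, lr_mlp, it);
    a_W2.step(P.W2, G.W2, lr_mlp, it); a_b2.step(P.b2, G.b2, lr_mlp, it);
    a_V1.step(P.V1, G.V1, lr_mlp, it); a_c1.step(P.c1, G.c1, lr_mlp, it);
    a_V2.step(P.V2, G.V2, lr_mlp, it); a_c2.step(P.c2, G.c2, lr_mlp, it);
    a_V3.step(P.V3, G.V3, lr_mlp, it); a_c3.step(P.c3, G.c3, lr_mlp, it);
    a_U1.step(P.U1, G.U1, lr_mlp, it); a_u1.step(P.u1, G.u1, lr_mlp, it);
    a_U2.step(P.U2, G.U2, lr_mlp, it); a_u2.step(P.u2, G.u2, lr_mlp, it);
    if (opt_exposure) a_E.step(P.E, G.E, lr_E, it);
    if (opt_pose) {
      a_dT.step(P.dT, G.dT, lr_pose, it);
      a_dTh.step(P.dTh, G.dTh, lr_pose, it);
    }
    if (it == 1 || it % log_every == 0 || it == n_iter) {
      log_iter.push_back(it);
      log_loss.push_back(loss);
    }
    if (it % 50 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["params"] = params_to_list(P, params),
                      _["log_iter"] = wrap(log_iter),
                      _["log_loss"] = wrap(log_loss));
}
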