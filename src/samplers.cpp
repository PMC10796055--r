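#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Target families: 0 gaussian, 1 scaled beta on [lo,hi],
// 2 flat on interval [lo,hi], 3 flat on a convex polygon (hex hull).
struct Target {
  int family;
  double p1, p2, lo, hi;
  NumericMatrix poly;
  int dim;
};

static Target read_target(const List& dom) {
  Target t;
  t.family = as<int>(dom["family"]);
  t.p1 = as<double>(dom["p1"]);
  t.p2 = as<double>(dom["p2"]);
  t.lo = as<double>(dom["lo"]);
  t.hi = as<double>(dom["hi"]);
  t.dim = as<int>(dom["dim"]);
  if (t.family == 3) t.poly = as<NumericMatrix>(dom["poly"]);
  return t;
}

static bool in_hull(const Target& t, const double* x) {
  int n = t.poly.nrow();
  for (int i = 0; i < n; ++i) {
    int j = (i + 1) % n;
    double ex = t.poly(j, 0) - t.poly(i, 0);
    double ey = t.poly(j, 1) - t.poly(i, 1);
    double cr = ex * (x[1] - t.poly(i, 1)) - ey * (x[0] - t.poly(i, 0));
    if (cr < -1e-12) return false;
  }
  return true;
}

// Unnormalised log density (normalising constants cancel in all ratios).
static double logdens(const Target& t, const double* x) {
  switch (t.family) {
  case 0: {
    double z = (x[0] - t.p1) / t.p2;
    return -0.5 * z * z;
  }
  case 1: {
    if (x[0] <= t.lo || x[0] >= t.hi) return R_NegInf;
    double z = (x[0] - t.lo) / (t.hi - t.lo);
    return (t.p1 - 1.0) * std::log(z) + (t.p2 - 1.0) * std::log(1.0 - z);
  }
  case 2:
    return (x[0] < t.lo || x[0] > t.hi) ? R_NegInf : 0.0;
  case 3:
    return in_hull(t, x) ? 0.0 : R_NegInf;
  }
  return R_NegInf;
}

static void gradld(const Target& t, const double* x, double* g) {
  g[0] = 0.0;
  if (t.dim == 2) g[1] = 0.0;
  if (t.family == 0) {
    g[0] = (t.p1 - x[0]) / (t.p2 * t.p2);
  } else if (t.family == 1) {
    double w = t.hi - t.lo;
    double z = (x[0] - t.lo) / w;
    g[0] = ((t.p1 - 1.0) / z - (t.p2 - 1.0) / (1.0 - z)) / w;
  }
}

// Reflect a position (and its momentum) back into the support.
static void reflect(const Target& t, double* x, double* p) {
  if (t.family == 1 || t.family == 2) {
    double lo = t.lo, hi = t.hi, w = hi - lo;
    int guard = 0;
    while ((x[0] < lo || x[0] > hi) && guard++ < 1000) {
      if (x[0] < lo) { x[0] = 2.0 * lo - x[0]; p[0] = -p[0]; }
      else           { x[0] = 2.0 * hi - x[0]; p[0] = -p[0]; }
    }
    // open support for the beta family: nudge off an exact boundary hit
    if (t.family == 1) {
      double eps = 1e-12 * w;
      if (x[0] <= lo) x[0] = lo + eps;
      if (x[0] >= hi) x[0] = hi - eps;
    }
  } else if (t.family == 3) {
    int n = t.poly.nrow();
    for (int it = 0; it < 64; ++it) {
      bool ok = true;
      for (int i = 0; i < n; ++i) {
        int j = (i + 1) % n;
        double ex = t.poly(j, 0) - t.poly(i, 0);
        double ey = t.poly(j, 1) - t.poly(i, 1);
        double len = std::sqrt(ex * ex + ey * ey);
        double nx = ey / len, ny = -ex / len; // outward normal (CCW polygon)
        double viol = (x[0] - t.poly(i, 0)) * nx + (x[1] - t.poly(i, 1)) * ny;
        if (viol > 0) {
          x[0] -= 2.0 * viol * nx;
          x[1] -= 2.0 * viol * ny;
          double pn = p[0] * nx + p[1] * ny;
          p[0] -= 2.0 * pn * nx;
          p[1] -= 2.0 * pn * ny;
          ok = false;
        }
      }
      if (ok) break;
    }
  }
}

// Standard leapfrog on the tempered density p(x)^(1/temp) with kinetic
// energy p^2 / (2 mass); positions reflect at support boundaries with
// momentum negation along the boundary normal.
static void leapfrog_run(const Target& t, double* x, double* p, double eps,
                         int L, double temp, double mass) {
  int d = t.dim;
  double g[2];
  gradld(t, x, g);
  for (int l = 0; l < L; ++l) {
    for (int k = 0; k < d; ++k) p[k] += 0.5 * eps * g[k] / temp;
    for (int k = 0; k < d; ++k) x[k] += eps * p[k] / mass;
    reflect(t, x, p);
    gradld(t, x, g);
    for (int k = 0; k < d; ++k) p[k] += 0.5 * eps * g[k] / temp;
  }
}

// [[Rcpp::export]]
List leapfrog_cpp(List dom, NumericVector x, NumericVector p, double eps,
                  int L, double temp = 1.0, double mass = 1.0) {
  Target t = read_target(dom);
  double xx[2] = {0, 0}, pp[2] = {0, 0};
  for (int k = 0; k < t.dim; ++k) { xx[k] = x[k]; pp[k] = p[k]; }
  leapfrog_run(t, xx, pp, eps, L, temp, mass);
  NumericVector xo(t.dim), po(t.dim);
  for (int k = 0; k < t.dim; ++k) { xo[k] = xx[k]; po[k] = pp[k]; }
  return List::create(_["position"] = xo, _["momentum"] = po);
}

// One unified driver for MH / MC3 / HMC / REC / MCHMC / MCREC.
// C chains target p(x)^(1/T_i) with T_i = (1+Delta)^(i-1); only the cold
// chain (T=1) is emitted. With C = 1 the coupling layer is bypassed
// entirely (no swap RNG draws), so single-chain models are exact
// reductions of their coupled counterparts under a shared seed stream.
// [[Rcpp::export]]
NumericMatrix run_chain_cpp(List dom, NumericVector start, bool use_gradient,
                            double sigma, double eps, int L, double psd,
                            double alpha, int C, double Delta, double s,
                            int n_emit, int burnin, bool negate_on_reject) {
  Target t = read_target(dom);
  int d = t.dim;
  double mass = psd * psd;
  RNGScope scope;

  std::vector<std::vector<double> > x(C, std::vector<double>(d));
  std::vector<std::vector<double> > p(C, std::vector<double>(d, 0.0));
  std::vector<double> lp(C);
  for (int i = 0; i < C; ++i) {
    for (int k = 0; k < d; ++k) x[i][k] = start[k];
    lp[i] = logdens(t, &x[i][0]);
    if (use_gradient)
      for (int k = 0; k < d; ++k) p[i][k] = psd * norm_rand();
  }

  NumericMatrix out(n_emit, d);
  int total = burnin + n_emit;
  double refresh = std::sqrt(1.0 - alpha * alpha);
  double x0[2], p0[2], g[2], y[2];
  (void)g;

  for (int it = 0; it < total; ++it) {
    for (int i = 0; i < C; ++i) {
      double Ti = std::pow(1.0 + Delta, i);
      if (use_gradient) {
        // partial momentum refreshment (alpha = 0: full refresh)
        for (int k = 0; k < d; ++k)
          p[i][k] = alpha * p[i][k] + refresh * psd * norm_rand();
        double K0 = 0.0;
        for (int k = 0; k < d; ++k) {
          x0[k] = x[i][k];
          p0[k] = p[i][k];
          K0 += p[i][k] * p[i][k];
        }
        K0 /= 2.0 * mass;
        double H0 = -lp[i] / Ti + K0;
        leapfrog_run(t, &x[i][0], &p[i][0], eps, L, Ti, mass);
        double lp1 = logdens(t, &x[i][0]);
        double K1 = 0.0;
        for (int k = 0; k < d; ++k) K1 += p[i][k] * p[i][k];
        K1 /= 2.0 * mass;
        double H1 = -lp1 / Ti + K1;
        if (R_finite(lp1) && unif_rand() < std::exp(H0 - H1)) {
          lp[i] = lp1;
        } else {
          for (int k = 0; k < d; ++k) {
            x[i][k] = x0[k];
            p[i][k] = negate_on_reject ? -p0[k] : p0[k];
          }
        }
      } else {
        for (int k = 0; k < d; ++k) y[k] = x[i][k] + sigma * norm_rand();
        double lp1 = logdens(t, y);
        double u = unif_rand();
        if (R_finite(lp1) && std::log(u) < (lp1 - lp[i]) / Ti) {
          for (int k = 0; k < d; ++k) x[i][k] = y[k];
          lp[i] = lp1;
        }
      }
    }
    if (C > 1 && unif_rand() < s) {
      // attempt one swap between a random neighbouring temperature pair
      int a = (int)(unif_rand() * (C - 1));
      if (a >= C - 1) a = C - 2;
      int b = a + 1;
      double Ta = std::pow(1.0 + Delta, a);
      double Tb = std::pow(1.0 + Delta, b);
      double lr = (lp[b] - lp[a]) * (1.0 / Ta - 1.0 / Tb);
      if (std::log(unif_rand()) < lr) {
        std::swap(x[a], x[b]);
        std::swap(p[a], p[b]);
        std::swap(lp[a], lp[b]);
      }
    }
    if (it >= burnin)
      for (int k = 0; k < d; ++k) out(it - burnin, k) = x[0][k];
  }
  return out;
}
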