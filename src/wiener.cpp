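// Wiener diffusion first-passage-time machinery.
//
// Conventions: evidence X(t) starts at z (absolute units, 0 < z < a),
// drifts at v with within-trial diffusion coefficient sigma, and is
// absorbed at 0 (lower) or a (upper).  Across-trial variability:
// v ~ Normal(DR, s), start ~ Uniform(z +/- sz/2), nondecision ~
// Uniform(Ter +/- st/2).  Densities are on the observed-RT scale
// (decision time + nondecision time) and are defective: each boundary's
// density integrates to that boundary's choice probability.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <map>
#include <random>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Gauss-Legendre nodes/weights on [-1, 1] (Newton iteration on P_n).
static void gauss_legendre_compute(int n, std::vector<double> &x, std::vector<double> &w) {
  x.assign(n, 0.0);
  w.assign(n, 0.0);
  int m = (n + 1) / 2;
  for (int i = 0; i < m; ++i) {
    double xi = std::cos(M_PI * (i + 0.75) / (n + 0.5));
    double pp = 0.0;
    for (int it = 0; it < 100; ++it) {
      double p1 = 1.0, p2 = 0.0;
      for (int j = 0; j < n; ++j) {
        double p3 = p2;
        p2 = p1;
        p1 = ((2.0 * j + 1.0) * xi * p2 - j * p3) / (j + 1.0);
      }
      pp = n * (xi * p1 - p2) / (xi * xi - 1.0);
      double dx = p1 / pp;
      xi -= dx;
      if (std::fabs(dx) < 1e-15) break;
    }
    x[i] = -xi;
    x[n - 1 - i] = xi;
    w[i] = 2.0 / ((1.0 - xi * xi) * pp * pp);
    w[n - 1 - i] = w[i];
  }
}

// cached nodes per order (orders in use are few and small)
typedef std::pair<std::vector<double>, std::vector<double> > glpair;
static const glpair &gl_nodes(int n) {
  static std::map<int, glpair> cache;
  std::map<int, glpair>::iterator it = cache.find(n);
  if (it == cache.end()) {
    glpair p;
    gauss_legendre_compute(n, p.first, p.second);
    it = cache.insert(std::make_pair(n, p)).first;
  }
  return it->second;
}

static void gauss_legendre(int n, std::vector<double> &x, std::vector<double> &w) {
  const glpair &p = gl_nodes(n);
  x = p.first;
  w = p.second;
}

// ---------------------------------------------------------------------------
// Drift-free lower-boundary FPT density at normalized time tau for unit
// boundary and relative start w, via the small-time / large-time series with
// the usual truncation bounds; the representation with fewer terms is used.
static double fnorm0(double tau, double w, double eps) {
  if (tau <= 0.0) return 0.0;
  double kl, ks;
  if (M_PI * tau * eps < 1.0) {
    kl = std::sqrt(-2.0 * std::log(M_PI * tau * eps) / (M_PI * M_PI * tau));
    kl = std::max(kl, 1.0 / (M_PI * std::sqrt(tau)));
  } else {
    kl = 1.0 / (M_PI * std::sqrt(tau));
  }
  if (2.0 * std::sqrt(2.0 * M_PI * tau) * eps < 1.0) {
    ks = 2.0 + std::sqrt(-2.0 * tau * std::log(2.0 * std::sqrt(2.0 * M_PI * tau) * eps));
    ks = std::max(ks, std::sqrt(tau) + 1.0);
  } else {
    ks = 2.0;
  }
  double p = 0.0;
  if (ks < kl) {
    int K = (int)std::ceil(ks);
    int lo = -((K - 1) / 2);
    int hi = (K - 1) / 2 + ((K - 1) % 2);
    for (int k = lo; k <= hi; ++k) {
      double q = w + 2.0 * k;
      p += q * std::exp(-q * q / (2.0 * tau));
    }
    p /= std::sqrt(2.0 * M_PI * tau * tau * tau);
  } else {
    int K = (int)std::ceil(kl);
    for (int k = 1; k <= K; ++k) {
      p += k * std::exp(-k * k * M_PI * M_PI * tau / 2.0) * std::sin(k * M_PI * w);
    }
    p *= M_PI;
  }
  return p > 0.0 ? p : 0.0;
}

// Lower-boundary density at decision time td, with the drift already
// marginalized over Normal(mu, eta^2) analytically: the drift-dependent
// factor exp(-A v - B v^2) (A = z/sigma^2, B = td/(2 sigma^2)) integrates
// against the normal to
//   exp((A^2 eta^2 - 2 A mu - 2 B mu^2) / (2 (1 + 2 B eta^2))) / sqrt(1 + 2 B eta^2).
static double wfpt_one(double td, double mu, double eta, double a, double zabs,
                       double sigma, bool upper, double eps) {
  if (td <= 0.0) return 0.0;
  double w = zabs / a;
  double m = mu;
  if (upper) {
    w = 1.0 - w;
    m = -mu;
  }
  double s2 = sigma * sigma;
  double tau = td * s2 / (a * a);
  double A = a * w / s2;
  double B = td / (2.0 * s2);
  double den = 1.0 + 2.0 * B * eta * eta;
  double expo = (A * A * eta * eta - 2.0 * A * m - 2.0 * B * m * m) / (2.0 * den);
  double M = std::exp(expo) / std::sqrt(den);
  return (s2 / (a * a)) * fnorm0(tau, w, eps) * M;
}

// Marginal density over uniform start and nondecision ranges (fixed-order
// Gauss-Legendre), at observed RT t.
static double wfpt_marg(double t, double mu, double eta, double a, double z,
                        double sz, double ter, double st, double sigma,
                        bool upper,
                        const std::vector<double> &zx, const std::vector<double> &zw,
                        const std::vector<double> &tx, const std::vector<double> &tw) {
  double out = 0.0;
  int nT = (st > 0.0) ? (int)tx.size() : 1;
  int nZ = (sz > 0.0) ? (int)zx.size() : 1;
  for (int i = 0; i < nT; ++i) {
    double teri = (st > 0.0) ? ter + 0.5 * st * tx[i] : ter;
    double wt = (st > 0.0) ? 0.5 * tw[i] : 1.0;
    double td = t - teri;
    if (td <= 0.0) continue;
    double inner = 0.0;
    for (int j = 0; j < nZ; ++j) {
      double zj = (sz > 0.0) ? z + 0.5 * sz * zx[j] : z;
      double wz = (sz > 0.0) ? 0.5 * zw[j] : 1.0;
      inner += wz * wfpt_one(td, mu, eta, a, zj, sigma, upper, 1e-12);
    }
    out += wt * inner;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Closed-form absorption probability at the upper boundary for fixed drift.
static double p_upper_fixed(double v, double a, double z, double sigma) {
  double s2 = sigma * sigma;
  double x = 2.0 * v * a / s2;
  if (std::fabs(x) < 1e-10) return z / a;
  if (x > 0.0) {
    // exponents negative: stable
    return std::expm1(-2.0 * v * z / s2) / std::expm1(-x);
  }
  // v < 0: multiply through by exp(x) to keep exponents <= 0
  double u = -v;
  double e1 = std::exp(-2.0 * u * a / s2);
  double e2 = std::exp(2.0 * u * (z - a) / s2);
  double num = e1 - e2;
  double den = e1 - 1.0;
  return num / den;
}

static double choice_prob_core(double mu, double eta, double a, double z, double sz,
                               double sigma, bool upper, int nv, int nz) {
  std::vector<double> vx, vw, zx, zw;
  gauss_legendre(nv, vx, vw);
  gauss_legendre(nz, zx, zw);
  double out = 0.0;
  int nV = (eta > 0.0) ? nv : 1;
  int nZ = (sz > 0.0) ? nz : 1;
  double wnorm = 0.0;
  for (int i = 0; i < nV; ++i) {
    double vi = mu, wv = 1.0;
    if (eta > 0.0) {
      vi = mu + 8.0 * eta * vx[i];
      // normal pdf weight times half-width (8 eta); renormalized below
      wv = vw[i] * 8.0 * eta *
           std::exp(-0.5 * std::pow((vi - mu) / eta, 2)) / (eta * std::sqrt(2.0 * M_PI));
    }
    wnorm += wv;
    double inner = 0.0;
    for (int j = 0; j < nZ; ++j) {
      double zj = (sz > 0.0) ? z + 0.5 * sz * zx[j] : z;
      double wz = (sz > 0.0) ? 0.5 * zw[j] : 1.0;
      inner += wz * p_upper_fixed(vi, a, zj, sigma);
    }
    out += wv * inner;
  }
  out /= (eta > 0.0) ? wnorm : 1.0;
  return upper ? out : 1.0 - out;
}

// [[Rcpp::export]]
double choice_prob_cpp(double mu, double eta, double a, double z, double sz,
                       double sigma, bool upper, int nv, int nz) {
  return choice_prob_core(mu, eta, a, z, sz, sigma, upper, nv, nz);
}

// [[Rcpp::export]]
NumericVector wfpt_density_cpp(NumericVector t, double mu, double eta, double a,
                               double z, double sz, double ter, double st,
                               double sigma, bool upper, int nz, int nt) {
  std::vector<double> zx, zw, tx, tw;
  gauss_legendre(nz, zx, zw);
  gauss_legendre(nt, tx, tw);
  int m = t.size();
  NumericVector out(m);
  for (int i = 0; i < m; ++i)
    out[i] = wfpt_marg(t[i], mu, eta, a, z, sz, ter, st, sigma, upper, zx, zw, tx, tw);
  return out;
}

// Defective CDF at a sorted vector of observed-RT edges, by cumulative
// Gauss-Legendre integration of the density over successive segments.
static void cdf_edges(const double *edges, int m, double mu, double eta, double a,
                      double z, double sz, double ter, double st,
                      double sigma, bool upper, int nseg, int nz, int nt,
                      double *out) {
  std::vector<double> zx, zw, tx, tw, sx, sw;
  gauss_legendre(nz, zx, zw);
  gauss_legendre(nt, tx, tw);
  gauss_legendre(nseg, sx, sw);
  // integration starts at the earliest possible RT; long segments are
  // subdivided so the fixed-order rule tracks the peaked density
  double hmax = std::max(0.05, 0.4 * (a * a) / (sigma * sigma));
  double t0 = std::max(0.0, ter - 0.5 * st - 1e-9);
  double acc = 0.0, prev = t0;
  for (int i = 0; i < m; ++i) {
    double e = edges[i];
    if (e > prev) {
      int nsub = (int)std::ceil((e - prev) / hmax);
      double len = (e - prev) / nsub;
      for (int s = 0; s < nsub; ++s) {
        double lo = prev + s * len, hi = lo + len;
        double half = 0.5 * (hi - lo), mid = 0.5 * (hi + lo);
        double seg = 0.0;
        for (int k = 0; k < nseg; ++k) {
          double tk = mid + half * sx[k];
          seg += sw[k] * wfpt_marg(tk, mu, eta, a, z, sz, ter, st, sigma, upper,
                                   zx, zw, tx, tw);
        }
        acc += half * seg;
      }
      prev = e;
    }
    out[i] = acc;
  }
}

// [[Rcpp::export]]
NumericVector wfpt_cdf_cpp(NumericVector edges, double mu, double eta, double a,
                           double z, double sz, double ter, double st,
                           double sigma, bool upper, int nseg, int nz, int nt) {
  NumericVector out(edges.size());
  if (edges.size())
    cdf_edges(&edges[0], edges.size(), mu, eta, a, z, sz, ter, st, sigma,
              upper, nseg, nz, nt, &out[0]);
  return out;
}

// Negative log-likelihood of one block's quantile-bin counts. Empty edge
// vectors with a single count denote a collapsed (single-cell) response.
// [[Rcpp::export]]
double block_negll_cpp(NumericVector edges_u, NumericVector counts_u,
                       NumericVector edges_l, NumericVector counts_l,
                       double mu, double eta, double a, double z, double sz,
                       double ter, double st, double sigma,
                       int nseg, int nz, int nt, double floor_p) {
  double pu = choice_prob_core(mu, eta, a, z, sz, sigma, true, 16, 6);
  double ll = 0.0;
  for (int side = 0; side < 2; ++side) {
    bool upper = (side == 0);
    NumericVector &edges = upper ? edges_u : edges_l;
    NumericVector &counts = upper ? counts_u : counts_l;
    double pb = upper ? pu : 1.0 - pu;
    int m = edges.size();
    if (m == 0) {
      if (counts.size() == 1 && counts[0] > 0)
        ll += counts[0] * std::log(std::max(pb, floor_p));
      continue;
    }
    std::vector<double> F(m);
    cdf_edges(&edges[0], m, mu, eta, a, z, sz, ter, st, sigma, upper,
              nseg, nz, nt, &F[0]);
    double prev = 0.0;
    for (int j = 0; j <= m; ++j) {
      double Fj = (j < m) ? F[j] : std::max(pb, F[m - 1]);
      double pbin = std::max(Fj - prev, 0.0);
      if (counts[j] > 0) ll += counts[j] * std::log(std::max(pbin, floor_p));
      prev = Fj;
    }
  }
  return -ll;
}

// ---------------------------------------------------------------------------
// Trial simulator: Euler-Maruyama with Brownian-bridge boundary-crossing
// correction within each step (reduces the boundary-overshoot bias so that
// moderate dt is accurate).  Own RNG stream seeded explicitly.
// [[Rcpp::export]]
List simulate_trials_cpp(int n, double mu, double eta, double a, double z,
                         double sz, double ter, double st, double sigma,
                         double dt, int seed, bool bridge, double tmax) {
  std::mt19937_64 rng((uint64_t)seed);
  std::normal_distribution<double> rnorm01(0.0, 1.0);
  std::uniform_real_distribution<double> runif01(0.0, 1.0);
  IntegerVector boundary(n); // 1 = upper, 0 = lower
  NumericVector rt(n);
  double sdt = sigma * std::sqrt(dt);
  for (int i = 0; i < n; ++i) {
    double vi = (eta > 0.0) ? mu + eta * rnorm01(rng) : mu;
    double xi = (sz > 0.0) ? z + sz * (runif01(rng) - 0.5) : z;
    double teri = (st > 0.0) ? ter + st * (runif01(rng) - 0.5) : ter;
    double t = 0.0;
    int b = -1;
    while (t < tmax) {
      double x0 = xi;
      xi += vi * dt + sdt * rnorm01(rng);
      t += dt;
      if (xi >= a) { b = 1; break; }
      if (xi <= 0.0) { b = 0; break; }
      if (bridge) {
        // probability the bridge between x0 and xi crossed a boundary
        double pu = std::exp(-2.0 * (a - x0) * (a - xi) / (sigma * sigma * dt));
        double pl = std::exp(-2.0 * x0 * xi / (sigma * sigma * dt));
        double u = runif01(rng);
        if (u < pu) { b = 1; break; }
        if (u < pu + pl) { b = 0; break; }
      }
    }
    if (b < 0) b = (xi > a / 2.0) ? 1 : 0; // pathological: force by position
    boundary[i] = b;
    rt[i] = t + teri;
  }
  return List::create(_["boundary"] = boundary, _["rt"] = rt);
}
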