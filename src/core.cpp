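#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Integer power: Hill coefficients are small positive integers, so repeated
// squaring is much cheaper than std::pow and exact.
static inline double ipow(double b, int e) {
  double r = 1.0;
  while (e > 0) {
    if (e & 1) r *= b;
    b *= b;
    e >>= 1;
  }
  return r;
}

// Shifted Hill multiplier: H(0) = 1, H(Inf) = lambda.
static inline double hill_shift(double x, double x0, int n, double lam) {
  return lam + (1.0 - lam) / (1.0 + ipow(x / x0, n));
}

struct Grn {
  int nn, ne;
  const double *g, *k, *lam, *x0;
  const int *nh, *src, *tgt;

  void rhs(const double *x, double *dx) const {
    for (int i = 0; i < nn; ++i) dx[i] = 1.0;
    for (int e = 0; e < ne; ++e)
      dx[tgt[e]] *= hill_shift(x[src[e]], x0[e], nh[e], lam[e]);
    for (int i = 0; i < nn; ++i) dx[i] = g[i] * dx[i] - k[i] * x[i];
  }
};

// Cash-Karp RK45 coefficients.
static const double B21 = 1.0 / 5.0;
static const double B31 = 3.0 / 40.0, B32 = 9.0 / 40.0;
static const double B41 = 3.0 / 10.0, B42 = -9.0 / 10.0, B43 = 6.0 / 5.0;
static const double B51 = -11.0 / 54.0, B52 = 5.0 / 2.0, B53 = -70.0 / 27.0,
                    B54 = 35.0 / 27.0;
static const double B61 = 1631.0 / 55296.0, B62 = 175.0 / 512.0,
                    B63 = 575.0 / 13824.0, B64 = 44275.0 / 110592.0,
                    B65 = 253.0 / 4096.0;
static const double C1 = 37.0 / 378.0, C3 = 250.0 / 621.0, C4 = 125.0 / 594.0,
                    C6 = 512.0 / 1771.0;
static const double D1 = C1 - 2825.0 / 27648.0, D3 = C3 - 18575.0 / 48384.0,
                    D4 = C4 - 13525.0 / 55296.0, D5 = -277.0 / 14336.0,
                    D6 = C6 - 1.0 / 4.0;

#define MAXN 64

// Relax one trajectory to a steady state.  Returns residual at exit;
// converged flag set when max |dx/dt| / max(x, 1) < tol before t_max.
static double relax(const Grn &grn, double *x, double tol, double t_max,
                    bool &converged) {
  int nn = grn.nn;
  double k1[MAXN], k2[MAXN], k3[MAXN], k4[MAXN], k5[MAXN], k6[MAXN],
      xt[MAXN], xe[MAXN], xn[MAXN];
  double t = 0.0, h = 0.05;
  const double hmax = 10.0, hmin = 1e-8, atol = 1e-8, rtol = 1e-6;
  converged = false;
  double res = R_PosInf;
  while (t < t_max) {
    grn.rhs(x, k1);
    // residual test on the accepted state
    res = 0.0;
    for (int i = 0; i < nn; ++i) {
      double r = std::fabs(k1[i]) / std::max(x[i], 1.0);
      if (r > res) res = r;
    }
    if (res < tol) { converged = true; return res; }
    if (h > t_max - t) h = t_max - t;
    // attempt a step, shrinking h until the error estimate passes
    for (;;) {
      for (int i = 0; i < nn; ++i) xt[i] = x[i] + h * B21 * k1[i];
      grn.rhs(xt, k2);
      for (int i = 0; i < nn; ++i)
        xt[i] = x[i] + h * (B31 * k1[i] + B32 * k2[i]);
      grn.rhs(xt, k3);
      for (int i = 0; i < nn; ++i)
        xt[i] = x[i] + h * (B41 * k1[i] + B42 * k2[i] + B43 * k3[i]);
      grn.rhs(xt, k4);
      for (int i = 0; i < nn; ++i)
        xt[i] = x[i] + h * (B51 * k1[i] + B52 * k2[i] + B53 * k3[i] +
                            B54 * k4[i]);
      grn.rhs(xt, k5);
      for (int i = 0; i < nn; ++i)
        xt[i] = x[i] + h * (B61 * k1[i] + B62 * k2[i] + B63 * k3[i] +
                            B64 * k4[i] + B65 * k5[i]);
      grn.rhs(xt, k6);
      double errmax = 0.0;
      bool bad = false;
      for (int i = 0; i < nn; ++i) {
        xn[i] = x[i] + h * (C1 * k1[i] + C3 * k3[i] + C4 * k4[i] + C6 * k6[i]);
        xe[i] = h * (D1 * k1[i] + D3 * k3[i] + D4 * k4[i] + D5 * k5[i] +
                     D6 * k6[i]);
        if (!R_finite(xn[i])) bad = true;
        double sc = atol + rtol * std::max(std::fabs(x[i]), std::fabs(xn[i]));
        double e = std::fabs(xe[i]) / sc;
        if (e > errmax) errmax = e;
      }
      if (!bad && errmax <= 1.0) {
        t += h;
        for (int i = 0; i < nn; ++i) x[i] = std::max(xn[i], 0.0);
        double fac = 0.9 * std::pow(std::max(errmax, 1e-10), -0.2);
        h *= std::min(5.0, fac);
        if (h > hmax) h = hmax;
        break;
      }
      h *= bad ? 0.1 : std::max(0.1, 0.9 * std::pow(errmax, -0.25));
      if (h < hmin) return res;  // step failure: give up, not converged
    }
  }
  return res;
}

// [[Rcpp::export]]
NumericVector cpp_ode_rhs(NumericVector x, NumericVector g, NumericVector k,
                          NumericVector lam, IntegerVector nh,
                          NumericVector x0, IntegerVector src,
                          IntegerVector tgt) {
  Grn grn{(int)x.size(), (int)src.size(), g.begin(), k.begin(), lam.begin(),
          x0.begin(), nh.begin(), src.begin(), tgt.begin()};
  NumericVector dx(x.size());
  grn.rhs(x.begin(), dx.begin());
  return dx;
}

// Integrate every row of `ics` to (attempted) steady state.
// [[Rcpp::export]]
List cpp_steady_states(NumericMatrix ics, NumericVector g, NumericVector k,
                       NumericVector lam, IntegerVector nh, NumericVector x0,
                       IntegerVector src, IntegerVector tgt, double tol,
                       double t_max) {
  int nn = g.size(), ni = ics.nrow();
  if (nn > MAXN) stop("network too large for the compiled core");
  Grn grn{nn, (int)src.size(), g.begin(), k.begin(), lam.begin(), x0.begin(),
          nh.begin(), src.begin(), tgt.begin()};
  NumericMatrix states(ni, nn);
  LogicalVector conv(ni);
  NumericVector resid(ni);
  double x[MAXN];
  for (int r = 0; r < ni; ++r) {
    for (int i = 0; i < nn; ++i) x[i] = ics(r, i);
    bool ok;
    resid[r] = relax(grn, x, tol, t_max, ok);
    conv[r] = ok;
    for (int i = 0; i < nn; ++i) states(r, i) = x[i];
  }
  return List::create(_["states"] = states, _["converged"] = conv,
                      _["residual"] = resid);
}

// Euler-Maruyama with per-node additive noise amplitude eta.
// Records the state every `record_every` steps (row 0 = initial state).
// [[Rcpp::export]]
NumericMatrix cpp_euler_maruyama(NumericVector x_init, NumericVector g,
                                 NumericVector k, NumericVector lam,
                                 IntegerVector nh, NumericVector x0,
                                 IntegerVector src, IntegerVector tgt,
                                 double dt, int n_steps, NumericVector eta,
                                 int record_every) {
  int nn = g.size();
  if (nn > MAXN) stop("network too large for the compiled core");
  Grn grn{nn, (int)src.size(), g.begin(), k.begin(), lam.begin(), x0.begin(),
          nh.begin(), src.begin(), tgt.begin()};
  int nrec = n_steps / record_every + 1;
  NumericMatrix out(nrec, nn);
  double x[MAXN], dx[MAXN];
  double sq = std::sqrt(dt);
  for (int i = 0; i < nn; ++i) {
    x[i] = x_init[i];
    out(0, i) = x[i];
  }
  int row = 1;
  for (int s = 1; s <= n_steps; ++s) {
    grn.rhs(x, dx);
    for (int i = 0; i < nn; ++i) {
      x[i] += dx[i] * dt + eta[i] * sq * norm_rand();
      if (x[i] < 0.0) x[i] = 0.0;
      if (std::fabs(x[i]) > 1e9)
        stop("numerical blow-up in Euler-Maruyama at step %d", s);
    }
    if (s % record_every == 0) {
      for (int i = 0; i < nn; ++i) out(row, i) = x[i];
      ++row;
    }
  }
  return out;
}
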