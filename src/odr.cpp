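// Foot-point projection for orthogonal distance regression.
//
// For each datum (t_obs, R_obs) find the local minimiser, nearest to
// `start`, of the squared distance (t_obs - t)^2 + (R_obs - f(t))^2 to
// a risk curve f. The stationarity function
//   g(t) = (t - t_obs) + f'(t) (f(t) - R_obs)
// (half the distance derivative) is bracketed by expanding from the
// start in the descent direction until it changes sign, then bisected.
// This is the compiled twin of the algorithm documented in R/fitting.R;
// curve evaluation is inlined per model family.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct Curve {
  int model; // 0 = plm, 1 = im/im2, 2 = im1
  double A, gamma, tau, C, alpha;

  inline void eval(double t, double &f, double &fp) const {
    if (model == 0) {
      f = std::exp(std::log(A) + gamma * std::log(t));
      fp = gamma * f / t;
    } else if (model == 2) {
      f = A * std::exp(alpha * t);
      fp = alpha * f;
    } else {
      double v = std::exp(-alpha * (t - tau));
      double w = std::exp(v);
      double den = w - C;
      f = A / den;
      fp = A * alpha * v * w / (den * den);
    }
  }

  inline double g(double t, double t_obs, double R_obs) const {
    double f, fp;
    eval(t, f, fp);
    return (t - t_obs) + fp * (f - R_obs);
  }
};

inline double clamp(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

} // namespace

// [[Rcpp::export(name = ".cpp_project")]]
NumericMatrix cpp_project(int model, NumericVector par, NumericVector t_obs,
                          NumericVector R_obs, NumericVector start,
                          double lo, double hi, int n_expand,
                          int n_bisect) {
  Curve c;
  c.model = model;
  c.A = par["A"];
  c.gamma = par.containsElementNamed("gamma") ? double(par["gamma"]) : 0.0;
  c.tau = par.containsElementNamed("tau") ? double(par["tau"]) : 0.0;
  c.C = par.containsElementNamed("C") ? double(par["C"]) : 0.0;
  c.alpha = par.containsElementNamed("alpha") ? double(par["alpha"]) : 0.0;

  const int m = t_obs.size();
  NumericMatrix out(m, 4); // t_proj, dist2, resid, converged
  colnames(out) = CharacterVector::create("t_proj", "dist2", "resid",
                                          "converged");

  for (int i = 0; i < m; ++i) {
    const double to = t_obs[i], Ro = R_obs[i];
    double s0 = clamp(start[i], lo + 1e-9, hi - 1e-9);
    double g0 = c.g(s0, to, Ro);
    double t_star = s0;
    bool found = false, boundary = false;
    if (!std::isfinite(g0)) {
      out(i, 0) = s0;
      out(i, 1) = NA_REAL;
      out(i, 2) = NA_REAL;
      out(i, 3) = 0.0;
      continue;
    }
    if (g0 == 0.0) {
      found = true;
    } else {
      const double dirn = g0 > 0 ? -1.0 : 1.0;
      double stp = std::max(0.25, 0.02 * std::fabs(s0));
      double a = s0, b = s0, ga = g0, gb = g0;
      for (int k = 0; k < n_expand; ++k) {
        double bn = clamp(b + dirn * stp, lo, hi);
        double gn = c.g(bn, to, Ro);
        if (std::isfinite(gn) && gn * g0 <= 0.0) {
          b = bn;
          gb = gn;
          found = true;
          break;
        }
        if (bn == lo || bn == hi) { // domain edge without a sign change
          boundary = true;
          b = bn;
          break;
        }
        a = bn;
        ga = gn;
        b = bn;
        gb = gn;
        stp *= 1.7;
      }
      if (found) {
        for (int k = 0; k < n_bisect && a != b; ++k) {
          double mid = 0.5 * (a + b);
          double gm = c.g(mid, to, Ro);
          if (ga * gm <= 0.0) {
            b = mid;
            gb = gm;
          } else {
            a = mid;
            ga = gm;
          }
        }
        t_star = 0.5 * (a + b);
      } else if (boundary) {
        t_star = b; // constrained minimum at the domain edge
      }
    }
    double f, fp;
    c.eval(t_star, f, fp);
    out(i, 0) = t_star;
    out(i, 1) = (to - t_star) * (to - t_star) + (Ro - f) * (Ro - f);
    out(i, 2) = (to - t_star) + fp * (Ro - f);
    out(i, 3) = found ? 1.0 : 0.0;
  }
  return out;
}
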