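#include <Rcpp.h>
#include <cmath>
#include <limits>
#include <vector>

using namespace Rcpp;

// epsilon-SVR dual in the net-coefficient parameterization beta_i = alpha_i
// - alpha*_i:
//
//   minimize  f(beta) = 1/2 beta' K beta - y' beta + eps * ||beta||_1
//   subject to sum(beta) = 0,  -C <= beta_i <= C
//
// Solved by sequential minimal optimization: at each iteration a working
// pair (i, j) is updated by the exact minimizer of the one-dimensional
// piecewise-quadratic restriction beta_i += t, beta_j -= t (which preserves
// the equality constraint). The KKT system for the equality multiplier
// lambda gives, per point, an admissible interval [lo_i, up_i]; optimality
// holds when max_i lo_i <= min_j up_j. The first index is the maximal
// violator (argmax lo); the second maximizes the second-order estimate of
// the objective decrease (lo_i - up_j)^2 / eta_ij, which avoids the
// zigzagging of pure maximal-violating-pair selection on ill-conditioned
// kernels. The bias equals lambda at the optimum, taken as the midpoint of
// the final interval.

static inline double snap(double v, double C) {
  double tol = 1e-10 * (1.0 + C);
  if (std::fabs(v - C) < tol) return C;
  if (std::fabs(v + C) < tol) return -C;
  if (std::fabs(v) < tol) return 0.0;
  return v;
}

// [[Rcpp::export(name = ".smo_svr")]]
List smo_svr(NumericMatrix K, NumericVector y, double C, double eps,
             double tol = 1e-6, int max_iter = 200000) {
  const int n = y.size();
  if (K.nrow() != n || K.ncol() != n)
    stop("kernel matrix dimensions do not match y");
  const double INF = std::numeric_limits<double>::infinity();

  std::vector<double> beta(n, 0.0);
  std::vector<double> g(n);            // g_i = (K beta)_i - y_i
  for (int i = 0; i < n; ++i) g[i] = -y[i];

  double lo_max = 0.0, up_min = 0.0;
  int iter = 0;
  bool converged = false;

  // exact gradient recomputation: incremental updates accumulate roundoff
  // over many iterations, which can stall the line search near the optimum
  auto refresh_gradient = [&]() {
    for (int i = 0; i < n; ++i) {
      double acc = 0.0;
      for (int k = 0; k < n; ++k) {
        if (beta[k] != 0.0) acc += K(i, k) * beta[k];
      }
      g[i] = acc - y[i];
    }
  };

  std::vector<double> lo_v(n), up_v(n);
  bool just_refreshed = false;
  for (iter = 0; iter < max_iter; ++iter) {
    if (iter % 2000 == 1999) refresh_gradient();
    lo_max = -INF; up_min = INF;
    int ii = -1;
    for (int i = 0; i < n; ++i) {
      double lo, up;
      if (beta[i] >= C) {
        lo = -INF;          up = -g[i] - eps;
      } else if (beta[i] > 0.0) {
        lo = -g[i] - eps;   up = lo;
      } else if (beta[i] == 0.0) {
        lo = -g[i] - eps;   up = -g[i] + eps;
      } else if (beta[i] > -C) {
        lo = -g[i] + eps;   up = lo;
      } else {
        lo = -g[i] + eps;   up = INF;
      }
      lo_v[i] = lo; up_v[i] = up;
      if (lo > lo_max) { lo_max = lo; ii = i; }
      if (up < up_min) { up_min = up; }
    }
    if (lo_max - up_min < tol) { converged = true; break; }

    // second index: maximal second-order decrease among violating partners
    int jj = -1;
    double best_est = -1.0;
    for (int j2 = 0; j2 < n; ++j2) {
      if (j2 == ii || !(up_v[j2] < lo_max)) continue;
      double d = lo_max - up_v[j2];
      double eta2 = K(ii, ii) + K(j2, j2) - 2.0 * K(ii, j2);
      if (eta2 < 1e-12) eta2 = 1e-12;
      double est = d * d / eta2;
      if (est > best_est) { best_est = est; jj = j2; }
    }
    if (jj < 0) {
      if (!just_refreshed) { refresh_gradient(); just_refreshed = true; continue; }
      break;
    }

    const int i = ii, j = jj;
    const double eta = K(i, i) + K(j, j) - 2.0 * K(i, j);
    const double gd = g[i] - g[j];
    const double tmin = std::max(-C - beta[i], beta[j] - C);
    const double tmax = std::min(C - beta[i], beta[j] + C);
    if (tmax <= tmin) {  // no feasible move (numerical corner)
      if (!just_refreshed) { refresh_gradient(); just_refreshed = true; continue; }
      break;
    }

    // candidate steps: box ends, kink points of the two |.| terms, and the
    // interior optimum of each smooth segment
    std::vector<double> knots;
    knots.push_back(tmin);
    knots.push_back(tmax);
    if (-beta[i] > tmin && -beta[i] < tmax) knots.push_back(-beta[i]);
    if (beta[j] > tmin && beta[j] < tmax) knots.push_back(beta[j]);
    std::sort(knots.begin(), knots.end());

    std::vector<double> cand(knots);
    if (eta > 0.0) {
      for (size_t s = 0; s + 1 < knots.size(); ++s) {
        double a = knots[s], b = knots[s + 1];
        if (b - a <= 0.0) continue;
        double mid = 0.5 * (a + b);
        double si = (beta[i] + mid > 0.0) ? 1.0 : ((beta[i] + mid < 0.0) ? -1.0 : 0.0);
        double sj = (beta[j] - mid > 0.0) ? 1.0 : ((beta[j] - mid < 0.0) ? -1.0 : 0.0);
        double t = -(gd + eps * (si - sj)) / eta;
        if (t > a && t < b) cand.push_back(t);
      }
    }

    double best_t = 0.0, best_phi = 0.0;  // phi(0) = 0
    for (size_t s = 0; s < cand.size(); ++s) {
      double t = cand[s];
      double phi = 0.5 * eta * t * t + gd * t
        + eps * (std::fabs(beta[i] + t) - std::fabs(beta[i]))
        + eps * (std::fabs(beta[j] - t) - std::fabs(beta[j]));
      if (phi < best_phi - 0.0) { best_phi = phi; best_t = t; }
    }
    if (best_phi >= -1e-15) {  // numerically stalled
      if (!just_refreshed) { refresh_gradient(); just_refreshed = true; continue; }
      break;
    }
    just_refreshed = false;

    beta[i] = snap(beta[i] + best_t, C);
    beta[j] = snap(beta[j] - best_t, C);
    for (int k = 0; k < n; ++k) g[k] += best_t * (K(k, i) - K(k, j));
  }
  refresh_gradient();  // final state reported from the exact gradient

  // bias = equality multiplier; recompute the interval at the final point
  {
    lo_max = -INF; up_min = INF;
    for (int i = 0; i < n; ++i) {
      double lo, up;
      if (beta[i] >= C) {
        lo = -INF;          up = -g[i] - eps;
      } else if (beta[i] > 0.0) {
        lo = up = -g[i] - eps;
      } else if (beta[i] == 0.0) {
        lo = -g[i] - eps;   up = -g[i] + eps;
      } else if (beta[i] > -C) {
        lo = up = -g[i] + eps;
      } else {
        lo = -g[i] + eps;   up = INF;
      }
      if (lo > lo_max) lo_max = lo;
      if (up < up_min) up_min = up;
    }
  }
  double bias;
  if (std::isfinite(lo_max) && std::isfinite(up_min)) {
    bias = 0.5 * (lo_max + up_min);
  } else if (std::isfinite(lo_max)) {
    bias = lo_max;
  } else if (std::isfinite(up_min)) {
    bias = up_min;
  } else {
    bias = 0.0;
  }

  double obj = 0.0, l1 = 0.0;
  for (int i = 0; i < n; ++i) {
    obj += 0.5 * beta[i] * (g[i] - y[i]);
    l1 += std::fabs(beta[i]);
  }
  obj += eps * l1;

  return List::create(
    _["beta"] = NumericVector(beta.begin(), beta.end()),
    _["bias"] = bias,
    _["objective"] = obj,
    _["iterations"] = iter,
    _["converged"] = converged,
    _["violation"] = std::max(0.0, lo_max - up_min));
}
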