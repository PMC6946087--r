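// Univariate linear-Gaussian state-space kernel.
//
// Model (annual log-biomass dynamics):
//   y_t = x_t + v_t,              v_t ~ N(0, r_t)        (r_t known per year)
//   x_t = phi * x_{t-1} + zb_t + w_t,  w_t ~ N(0, q)
//   x_1 ~ N(y_1, r_1)             (prior pinned at the first observation)
//
// zb_t = Z_t %*% beta is passed in already multiplied out where possible.
// Missing observations are encoded as NaN in y and handled by
// prediction-only steps.  Because the x_1 prior is centered at the observed
// y_1 it carries no free parameters, so EM monotonicity holds exactly.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double LOG2PI = 1.8378770664093454836;

// Forward filter; returns log-likelihood and (optionally) filtered moments.
static double filter_pass(const arma::vec& y, const arma::vec& r,
                          const arma::vec& zb, double phi, double q,
                          arma::vec* apred, arma::vec* Ppred,
                          arma::vec* afilt, arma::vec* Pfilt) {
  int n = y.n_elem;
  double ll = 0.0;
  double ap = y(0), Pp = r(0);  // prior for x_1
  double af, Pf;
  for (int t = 0; t < n; ++t) {
    if (t > 0) {
      ap = phi * af + zb(t);
      Pp = phi * phi * Pf + q;
    }
    if (apred) { (*apred)(t) = ap; (*Ppred)(t) = Pp; }
    if (std::isfinite(y(t))) {
      double F = Pp + r(t);
      if (!(F > 0.0) || !std::isfinite(F)) return -std::numeric_limits<double>::infinity();
      double v = y(t) - ap;
      ll += -0.5 * (LOG2PI + std::log(F) + v * v / F);
      double K = Pp / F;
      af = ap + K * v;
      Pf = Pp * (1.0 - K);
    } else {
      af = ap;
      Pf = Pp;
    }
    if (afilt) { (*afilt)(t) = af; (*Pfilt)(t) = Pf; }
  }
  return ll;
}

// [[Rcpp::export(name = ".kalman_loglik_cpp")]]
double kalman_loglik_cpp(const arma::vec& y, const arma::vec& r,
                         const arma::vec& zb, double phi, double q) {
  if (q < 0.0 || !std::isfinite(phi) || !std::isfinite(q))
    return -std::numeric_limits<double>::infinity();
  return filter_pass(y, r, zb, phi, q, nullptr, nullptr, nullptr, nullptr);
}

// Rauch-Tung-Striebel smoother.  Returns smoothed means, variances and
// lag-one cross covariances Cov(x_t, x_{t-1} | Y) for t = 2..n.
// [[Rcpp::export(name = ".kalman_smoother_cpp")]]
List kalman_smoother_cpp(const arma::vec& y, const arma::vec& r,
                         const arma::vec& zb, double phi, double q) {
  int n = y.n_elem;
  arma::vec ap(n), Pp(n), af(n), Pf(n);
  double ll = filter_pass(y, r, zb, phi, q, &ap, &Pp, &af, &Pf);
  arma::vec xs(n), Ps(n), Pcross(n, arma::fill::zeros);
  xs(n - 1) = af(n - 1);
  Ps(n - 1) = Pf(n - 1);
  for (int t = n - 2; t >= 0; --t) {
    double J = (Pp(t + 1) > 0.0) ? Pf(t) * phi / Pp(t + 1) : 0.0;
    xs(t) = af(t) + J * (xs(t + 1) - ap(t + 1));
    Ps(t) = Pf(t) + J * J * (Ps(t + 1) - Pp(t + 1));
    Pcross(t + 1) = J * Ps(t + 1);  // Cov(x_{t+1}, x_t | Y)
  }
  return List::create(_["loglik"] = ll, _["xs"] = xs, _["Ps"] = Ps,
                      _["Pcross"] = Pcross, _["apred"] = ap, _["Ppred"] = Pp,
                      _["afilt"] = af, _["Pfilt"] = Pf);
}

// EM with closed-form M-steps.  Z is n x k (k may be 0).  Returns the
// parameter estimates, the log-likelihood trace and a convergence flag.
// [[Rcpp::export(name = ".kalman_em_cpp")]]
List kalman_em_cpp(const arma::vec& y, const arma::vec& r, const arma::mat& Z,
                   double phi0, const arma::vec& beta0, double q0,
                   double tol, int max_iter, double q_min) {
  int n = y.n_elem;
  int k = Z.n_cols;
  double phi = phi0, q = std::max(q0, q_min);
  arma::vec beta = beta0;

  arma::vec ap(n), Pp(n), af(n), Pf(n), xs(n), Ps(n), Pcross(n);
  std::vector<double> trace;
  trace.reserve(64);
  double ll_old = -std::numeric_limits<double>::infinity();
  bool converged = false;
  int iter = 0;

  for (iter = 0; iter < max_iter; ++iter) {
    arma::vec zb = (k > 0) ? arma::vec(Z * beta) : arma::vec(n, arma::fill::zeros);

    // E-step: filter + smoother at current parameters
    double ll = filter_pass(y, r, zb, phi, q, &ap, &Pp, &af, &Pf);
    if (!std::isfinite(ll)) break;
    trace.push_back(ll);
    xs(n - 1) = af(n - 1);
    Ps(n - 1) = Pf(n - 1);
    Pcross.zeros();
    for (int t = n - 2; t >= 0; --t) {
      double J = (Pp(t + 1) > 0.0) ? Pf(t) * phi / Pp(t + 1) : 0.0;
      xs(t) = af(t) + J * (xs(t + 1) - ap(t + 1));
      Ps(t) = Pf(t) + J * J * (Ps(t + 1) - Pp(t + 1));
      Pcross(t + 1) = J * Ps(t + 1);
    }

    if (std::abs(ll - ll_old) < tol * (std::abs(ll_old) + 1.0) && iter > 0) {
      converged = true;
      break;
    }
    ll_old = ll;

    // Sufficient statistics over t = 2..n (the x_1 prior is parameter-free)
    // Unknowns theta = (phi, beta); normal equations A theta = b.
    int m = 1 + k;
    arma::mat A(m, m, arma::fill::zeros);
    arma::vec b(m, arma::fill::zeros);
    for (int t = 1; t < n; ++t) {
      double Exx  = Ps(t - 1) + xs(t - 1) * xs(t - 1);   // E[x_{t-1}^2]
      double Excur = Pcross(t) + xs(t) * xs(t - 1);      // E[x_t x_{t-1}]
      A(0, 0) += Exx;
      b(0) += Excur;
      for (int i = 0; i < k; ++i) {
        A(0, i + 1) += Z(t, i) * xs(t - 1);
        A(i + 1, 0) += Z(t, i) * xs(t - 1);
        b(i + 1) += Z(t, i) * xs(t);
        for (int j = 0; j < k; ++j) A(i + 1, j + 1) += Z(t, i) * Z(t, j);
      }
    }
    arma::vec theta;
    bool ok = arma::solve(theta, A, b, arma::solve_opts::no_approx);
    if (!ok) break;
    phi = theta(0);
    for (int i = 0; i < k; ++i) beta(i) = theta(i + 1);

    // q update with the refreshed (phi, beta)
    double ssq = 0.0;
    for (int t = 1; t < n; ++t) {
      double zbt = 0.0;
      for (int i = 0; i < k; ++i) zbt += Z(t, i) * beta(i);
      double Ext2  = Ps(t) + xs(t) * xs(t);
      double Exx   = Ps(t - 1) + xs(t - 1) * xs(t - 1);
      double Excur = Pcross(t) + xs(t) * xs(t - 1);
      ssq += Ext2 - 2.0 * phi * Excur - 2.0 * zbt * xs(t) +
             phi * phi * Exx + 2.0 * phi * zbt * xs(t - 1) + zbt * zbt;
    }
    q = std::max(ssq / double(n - 1), q_min);
  }

  double ll_final = trace.empty() ? R_NegInf : trace.back();
  return List::create(_["phi"] = phi, _["beta"] = beta, _["sigma2_proc"] = q,
                      _["loglik"] = ll_final, _["trace"] = wrap(trace),
                      _["iterations"] = iter, _["converged"] = converged);
}

// Simulate one replicate series from the fitted model for the parametric
// bootstrap: x_1 ~ N(y1_anchor, r_1), then the AR recursion, observed with
// noise wherever obs_pattern is TRUE.  eps are pre-drawn N(0,1) deviates
// (length 2n) so that R controls the RNG stream.
// [[Rcpp::export(name = ".kalman_simulate_cpp")]]
arma::vec kalman_simulate_cpp(double y1_anchor, const arma::vec& r,
                              const arma::vec& zb, double phi, double q,
                              const LogicalVector& obs_pattern,
                              const arma::vec& eps) {
  int n = r.n_elem;
  arma::vec y(n);
  double x = y1_anchor + std::sqrt(r(0)) * eps(0);
  for (int t = 0; t < n; ++t) {
    if (t > 0) x = phi * x + zb(t) + std::sqrt(q) * eps(t);
    if (obs_pattern[t]) {
      y(t) = x + std::sqrt(r(t)) * eps(n + t);
    } else {
      y(t) = NA_REAL;
    }
  }
  return y;
}
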