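#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Damped fixed-point iteration for the steady state of a sigmoidal
// recurrent rate network:  s <- (1 - alpha) * s + alpha * g(h + K s),
// where h = W x is precomputed by the caller and g is the logistic.
// Convergence criterion: max-abs change in s between iterations <= tol.
// The iteration count is the operational "convergence time" used for
// critical-slowing-down diagnostics, so it must be counted identically
// for every call (fresh start from s0, no warm starts here).
// [[Rcpp::export(name = ".steady_state_cpp")]]
List steady_state_cpp(const arma::vec& h, const arma::mat& K,
                      const arma::vec& s0, double alpha, double tol,
                      int max_iter) {
  arma::vec s = s0;
  double resid = R_PosInf;
  bool converged = false;
  int it = 0;
  for (it = 1; it <= max_iter; ++it) {
    arma::vec u = h + K * s;
    arma::vec snew = (1.0 - alpha) * s + alpha / (1.0 + arma::exp(-u));
    resid = arma::abs(snew - s).max();
    s = snew;
    if (!s.is_finite()) {
      stop("steady-state iteration produced non-finite activities");
    }
    if (resid <= tol) {
      converged = true;
      break;
    }
  }
  if (it > max_iter) it = max_iter;
  return List::create(_["s"] = s, _["iterations"] = it,
                      _["converged"] = converged, _["residual"] = resid);
}

static inline double logis(double u) { return 1.0 / (1.0 + std::exp(-u)); }
static inline double logis_prime(double u) {
  double e = std::exp(-std::fabs(u));
  return e / ((1.0 + e) * (1.0 + e));
}

// Stochastic infomax training of the two cross-modal weights of the
// two-unit model. Feedforward is diag(w1, w2); inputs are independent
// zero-mean Gaussians. Per sample the update direction for (K12, K21) has
// a closed form (phi, chi and Gamma collapse to scalars for an invertible
// 2x2 susceptibility):
//   grad12 = g1 g2 K21 / D + s2 ((1-2 s1) + g1 K21 (1-2 s2)) / D^2
//   grad21 = g1 g2 K12 / D + s1 ((1-2 s2) + g2 K12 (1-2 s1)) / D^2
// with g_i = g'(u_i) and D = 1 - g1 g2 K12 K21. Near-singular samples
// (|D| tiny) are skipped and counted. Draws use the R RNG, so runs are
// reproducible under set.seed().
// [[Rcpp::export(name = ".simple_train_cpp")]]
List simple_train_cpp(double w1, double w2, double sig1, double sig2,
                      double k12, double k21, double eta, int n_updates,
                      int batch, double alpha, double tol, int max_iter) {
  int n_skipped = 0;
  long long total_iter = 0;
  for (int t = 0; t < n_updates; ++t) {
    double acc12 = 0.0, acc21 = 0.0;
    bool ok = true;
    for (int b = 0; b < batch; ++b) {
      double h1 = w1 * R::rnorm(0.0, sig1);
      double h2 = w2 * R::rnorm(0.0, sig2);
      // damped fixed-point iteration from the recurrence-free start
      double s1 = logis(h1), s2 = logis(h2);
      bool conv = false;
      for (int it = 1; it <= max_iter; ++it) {
        double n1 = (1.0 - alpha) * s1 + alpha * logis(h1 + k12 * s2);
        double n2 = (1.0 - alpha) * s2 + alpha * logis(h2 + k21 * s1);
        double r = std::max(std::fabs(n1 - s1), std::fabs(n2 - s2));
        s1 = n1; s2 = n2;
        ++total_iter;
        if (r <= tol) { conv = true; break; }
      }
      if (!conv) { ok = false; break; }
      double u1 = h1 + k12 * s2, u2 = h2 + k21 * s1;
      double g1 = logis_prime(u1), g2 = logis_prime(u2);
      double D = 1.0 - g1 * g2 * k12 * k21;
      if (std::fabs(D) < 1e-12) { ok = false; break; }
      acc12 += g1 * g2 * k21 / D
             + s2 * ((1.0 - 2.0 * s1) + g1 * k21 * (1.0 - 2.0 * s2)) / (D * D);
      acc21 += g1 * g2 * k12 / D
             + s1 * ((1.0 - 2.0 * s2) + g2 * k12 * (1.0 - 2.0 * s1)) / (D * D);
    }
    if (!ok) { ++n_skipped; continue; }
    k12 += eta * acc12 / batch;
    k21 += eta * acc21 / batch;
    if (!std::isfinite(k12) || !std::isfinite(k21)) {
      stop("cross-talk weights diverged to non-finite values");
    }
  }
  return List::create(_["k12"] = k12, _["k21"] = k21,
                      _["n_skipped"] = n_skipped,
                      _["mean_iterations"] =
                        (double)total_iter / ((double)n_updates * batch));
}

// Expected infomax update direction for (K12, K21) of the two-unit model,
// by tensor-product quadrature over the two input Gaussians. x1/q1 and
// x2/q2 are the per-dimension nodes (already scaled to input units) and
// normalized weights (summing to 1). Same closed-form per-sample gradient
// as the stochastic trainer above.
// [[Rcpp::export(name = ".simple_update_map_cpp")]]
NumericVector simple_update_map_cpp(double w1, double w2,
                                    const arma::vec& x1, const arma::vec& q1,
                                    const arma::vec& x2, const arma::vec& q2,
                                    double k12, double k21, double alpha,
                                    double tol, int max_iter) {
  double F12 = 0.0, F21 = 0.0;
  for (arma::uword i = 0; i < x1.n_elem; ++i) {
    double h1 = w1 * x1(i);
    for (arma::uword j = 0; j < x2.n_elem; ++j) {
      double h2 = w2 * x2(j);
      double s1 = logis(h1), s2 = logis(h2);
      bool conv = false;
      for (int it = 1; it <= max_iter; ++it) {
        double n1 = (1.0 - alpha) * s1 + alpha * logis(h1 + k12 * s2);
        double n2 = (1.0 - alpha) * s2 + alpha * logis(h2 + k21 * s1);
        double r = std::max(std::fabs(n1 - s1), std::fabs(n2 - s2));
        s1 = n1; s2 = n2;
        if (r <= tol) { conv = true; break; }
      }
      if (!conv) stop("steady state did not converge at quadrature node");
      double u1 = h1 + k12 * s2, u2 = h2 + k21 * s1;
      double g1 = logis_prime(u1), g2 = logis_prime(u2);
      double D = 1.0 - g1 * g2 * k12 * k21;
      if (std::fabs(D) < 1e-12) {
        stop("singular susceptibility at quadrature node: outside analysable regime");
      }
      double wgt = q1(i) * q2(j);
      F12 += wgt * (g1 * g2 * k21 / D
             + s2 * ((1.0 - 2.0 * s1) + g1 * k21 * (1.0 - 2.0 * s2)) / (D * D));
      F21 += wgt * (g1 * g2 * k12 / D
             + s1 * ((1.0 - 2.0 * s2) + g2 * k12 * (1.0 - 2.0 * s1)) / (D * D));
    }
  }
  return NumericVector::create(F12, F21);
}
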