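// Cyclic coordinate descent for the generalized elastic net.
//
// Minimizes
//   (1/2n) sum_i a_i (y_i - w'x_i - b)^2
//     + lambda1 * sum_j d_j |w_j| + (lambda2/2) w' P w
// one coordinate at a time, with soft-thresholding, followed by a
// closed-form bias update after each sweep.  The residual vector and P w
// are maintained incrementally.  When `skip_zero` is set, coordinates
// currently at zero whose soft-threshold argument stays inside
// lambda1*d_k are skipped; skipping leaves every state vector bitwise
// untouched, so the two paths produce identical models.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double soft(double v, double gamma) {
  if (v > gamma) return v - gamma;
  if (v < -gamma) return v + gamma;
  return 0.0;
}

// [[Rcpp::export(name = ".cd_gelnet")]]
List cd_gelnet(const arma::mat& X, const arma::vec& y, const arma::vec& a,
               double lambda1, double lambda2, const arma::vec& d,
               const arma::mat& P, bool identity_P,
               arma::vec w, double b,
               double tol, int max_iter, bool relative_tol,
               bool skip_zero) {
  const int n = X.n_rows;
  const int p = X.n_cols;
  const double sum_a = arma::accu(a);

  // per-coordinate curvature of the loss: z_k = (1/n) sum_i a_i x_ik^2
  arma::vec z(p);
  for (int k = 0; k < p; ++k) {
    z(k) = arma::dot(a % X.col(k), X.col(k)) / n;
  }

  arma::vec r = y - X * w - b;          // residuals
  arma::vec Pw = identity_P ? w : arma::vec(P * w);

  bool zero_denom_seen = false;

  auto objective = [&]() -> double {
    double loss = arma::dot(a, r % r) / (2.0 * n);
    double l1 = lambda1 * arma::dot(d, arma::abs(w));
    double l2 = 0.5 * lambda2 * arma::dot(w, Pw);
    return loss + l1 + l2;
  };

  std::vector<double> trace;
  double obj_prev = objective();
  bool converged = false;
  int iter = 0;

  for (iter = 1; iter <= max_iter; ++iter) {
    for (int k = 0; k < p; ++k) {
      const double Pkk = identity_P ? 1.0 : P(k, k);
      const double den = z(k) + lambda2 * Pkk;
      const double c = arma::dot(a % X.col(k), r) / n;
      const double num = c + w(k) * z(k)
        - lambda2 * (Pw(k) - Pkk * w(k));
      const double gamma = lambda1 * d(k);

      if (den <= 0.0) {
        // all-zero column with no quadratic penalty on it: hold at 0
        if (w(k) != 0.0) {
          const double delta = -w(k);
          r -= delta * X.col(k);
          if (identity_P) Pw(k) += delta; else Pw += delta * P.col(k);
          w(k) = 0.0;
        }
        zero_denom_seen = true;
        continue;
      }

      if (skip_zero && w(k) == 0.0 && std::abs(num) <= gamma) continue;

      const double w_new = soft(num, gamma) / den;
      const double delta = w_new - w(k);
      r -= delta * X.col(k);
      if (identity_P) Pw(k) += delta; else Pw += delta * P.col(k);
      w(k) = w_new;
    }

    // bias: weighted average of residuals about the current fit
    const double b_shift = arma::dot(a, r) / sum_a;
    b += b_shift;
    r -= b_shift;

    const double obj = objective();
    trace.push_back(obj);
    const double change = std::abs(obj_prev - obj);
    const double thresh = relative_tol
      ? tol * std::max(1.0, std::abs(obj_prev)) : tol;
    obj_prev = obj;
    if (change >= thresh) continue;
    // objective has stalled; accept only once first-order (KKT)
    // optimality holds within 10*tol, otherwise keep sweeping
    double viol = 0.0;
    for (int k = 0; k < p; ++k) {
      const double Pkk = identity_P ? 1.0 : P(k, k);
      if (z(k) + lambda2 * Pkk <= 0.0) continue;  // frozen coordinate
      const double g = arma::dot(a % X.col(k), r) / n - lambda2 * Pw(k);
      const double v = (w(k) != 0.0)
        ? std::abs(g - lambda1 * d(k) * ((w(k) > 0) - (w(k) < 0)))
        : std::max(std::abs(g) - lambda1 * d(k), 0.0);
      viol = std::max(viol, v);
    }
    if (viol < 10.0 * tol) { converged = true; break; }
  }
  if (iter > max_iter) iter = max_iter;

  return List::create(
    _["w"] = w, _["b"] = b, _["n_iter"] = iter,
    _["objective_trace"] = trace, _["converged"] = converged,
    _["zero_denom"] = zero_denom_seen);
}

// Inner solve for the penalized PCA iteration:
//   argmin_w  -g'w + lambda1 sum_j d_j |w_j| + (lambda2/2) w' P w
// by cyclic coordinate descent (strictly convex when lambda2*P_kk > 0).

// [[Rcpp::export(name = ".cd_linear_quad")]]
List cd_linear_quad(const arma::vec& g, double lambda1, double lambda2,
                    const arma::vec& d, const arma::mat& P, bool identity_P,
                    arma::vec w, double tol, int max_iter) {
  const int p = g.n_elem;
  arma::vec Pw = identity_P ? w : arma::vec(P * w);
  bool converged = false;
  int iter = 0;

  for (iter = 1; iter <= max_iter; ++iter) {
    double max_change = 0.0;
    for (int k = 0; k < p; ++k) {
      const double Pkk = identity_P ? 1.0 : P(k, k);
      const double den = lambda2 * Pkk;
      if (den <= 0.0) {  // no curvature: only the zero solution is bounded
        if (w(k) != 0.0) {
          const double delta = -w(k);
          if (identity_P) Pw(k) += delta; else Pw += delta * P.col(k);
          w(k) = 0.0;
        }
        continue;
      }
      const double num = g(k) - lambda2 * (Pw(k) - Pkk * w(k));
      const double w_new = soft(num, lambda1 * d(k)) / den;
      const double delta = w_new - w(k);
      if (delta != 0.0) {
        if (identity_P) Pw(k) += delta; else Pw += delta * P.col(k);
        w(k) = w_new;
        max_change = std::max(max_change, std::abs(delta));
      }
    }
    if (max_change < tol) { converged = true; break; }
  }
  if (iter > max_iter) iter = max_iter;

  return List::create(_["w"] = w, _["n_iter"] = iter,
                      _["converged"] = converged);
}
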