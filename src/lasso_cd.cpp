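// Penalized logistic regression solver used throughout the package.
//
// Solves  min_{b0, delta}  (1/n) sum_i nll(b0 + x_i'delta + o_i; y_i)
//                          + lambda * ||delta||_1
// by proximal Newton: an outer IRLS quadratic approximation, an inner
// cyclic coordinate descent with soft-thresholding, and a backtracking
// line search on the exact objective so the recorded objective trace is
// non-increasing.  Coordinates are screened into a candidate set by the
// gradient at the warm start; the screen is exact because the full KKT
// conditions are re-checked at convergence and any violator is added
// before continuing.  The intercept b0 is never penalized.  A nonzero
// penalty center c (transfer learning towards a source coefficient
// vector) is handled by the caller via delta = beta - c and o = X c.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double log1pexp_stable(double x) {
  // log(1 + exp(x)), stable for |x| up to ~700 and beyond
  if (x > 35.0) return x + std::exp(-x);
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

static double objective(const arma::vec& eta, const arma::vec& y,
                        const arma::vec& delta, double lambda) {
  double nll = 0.0;
  const arma::uword n = eta.n_elem;
  for (arma::uword i = 0; i < n; ++i) {
    nll += log1pexp_stable(eta(i)) - y(i) * eta(i);
  }
  return nll / static_cast<double>(n) + lambda * arma::accu(arma::abs(delta));
}

static inline double soft(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

// One cycle of coordinate descent over the given coordinate set.
// WX holds w .* x_j for the screened columns (BLAS-friendly inner
// products). Returns the largest |change| * sqrt(wx2).
static double cd_cycle(const arma::mat& X, const arma::mat& WX,
                       const arma::vec& w,
                       const arma::vec& wx2, double lambda,
                       const std::vector<arma::uword>& coords,
                       arma::vec& d, double& b0, double wsum,
                       arma::vec& r, double dn) {
  double maxch = 0.0;
  // intercept
  double b0_up = arma::dot(w, r) / wsum;
  if (b0_up != 0.0) {
    r -= b0_up;
    b0 += b0_up;
    double ch = std::fabs(b0_up) * std::sqrt(wsum / dn);
    if (ch > maxch) maxch = ch;
  }
  for (arma::uword jj = 0; jj < coords.size(); ++jj) {
    const arma::uword j = coords[jj];
    if (wx2(j) <= 0) continue;
    double rho = arma::dot(WX.unsafe_col(jj), r) / dn + wx2(j) * d(j);
    double dj = soft(rho, lambda) / wx2(j);
    double diff = dj - d(j);
    if (diff != 0.0) {
      r -= X.unsafe_col(j) * diff;
      d(j) = dj;
      double ch = std::fabs(diff) * std::sqrt(wx2(j));
      if (ch > maxch) maxch = ch;
    }
  }
  return maxch;
}

// Penalized-part gradient (1/n) X'(mu - y) at the current eta.
static arma::vec full_gradient(const arma::mat& X, const arma::vec& y,
                               const arma::vec& eta) {
  const arma::uword n = X.n_rows;
  arma::vec res(n);
  for (arma::uword i = 0; i < n; ++i)
    res(i) = 1.0 / (1.0 + std::exp(-eta(i))) - y(i);
  return X.t() * res / static_cast<double>(n);
}

// One proximal-Newton fit at a single lambda, warm-startable.
// [[Rcpp::export(name = ".cd_lasso_logistic")]]
List cd_lasso_logistic(const arma::mat& X, const arma::vec& y,
                       double lambda, const arma::vec& offset,
                       arma::vec delta, double b0,
                       double tol = 1e-8, int max_outer = 500,
                       int max_inner = 100) {
  const arma::uword n = X.n_rows, p = X.n_cols;
  const double dn = static_cast<double>(n);
  const double inner_tol = std::max(std::sqrt(tol) * 1e-2, 1e-7);

  arma::vec eta = b0 + X * delta + offset;
  double obj = objective(eta, y, delta, lambda);
  std::vector<double> trace;
  trace.push_back(obj);
  bool converged = false;

  // gradient screen at the warm start; exact via KKT re-check below
  std::vector<bool> in_set(p, false);
  std::vector<arma::uword> coords;
  {
    arma::vec g = full_gradient(X, y, eta);
    for (arma::uword j = 0; j < p; ++j) {
      if (delta(j) != 0.0 || std::fabs(g(j)) >= 0.9 * lambda) {
        in_set[j] = true;
        coords.push_back(j);
      }
    }
  }

  int total_outer = 0;
  for (int screen_round = 0; screen_round < 50; ++screen_round) {
    bool inner_converged = false;
    for (; total_outer < max_outer; ++total_outer) {
      // IRLS weights and working residual (for the b0 + X*delta part)
      arma::vec w(n), r(n);
      for (arma::uword i = 0; i < n; ++i) {
        double m = 1.0 / (1.0 + std::exp(-eta(i)));
        if (m < 1e-5) m = 1e-5;             // glmnet-style clamp: keeps
        if (m > 1.0 - 1e-5) m = 1.0 - 1e-5; // the working residual bounded
        double wi = m * (1.0 - m);
        w(i) = wi;
        r(i) = (y(i) - m) / wi;
      }
      arma::vec wx2(p, arma::fill::zeros);
      arma::mat WX(n, coords.size());
      for (arma::uword jj = 0; jj < coords.size(); ++jj) {
        const arma::uword j = coords[jj];
        WX.col(jj) = w % X.col(j);
        wx2(j) = arma::dot(WX.col(jj), X.col(j)) / dn;
      }
      double wsum = arma::accu(w);

      arma::vec d_new = delta;
      double b0_new = b0;
      for (int it = 0; it < max_inner; ++it) {
        double ch = cd_cycle(X, WX, w, wx2, lambda, coords, d_new, b0_new,
                             wsum, r, dn);
        if (ch < inner_tol) break;
      }

      // backtracking line search on the exact objective (guarantees a
      // monotone trace even when the quadratic model overshoots)
      arma::vec eta_new = b0_new + X * d_new + offset;
      double obj_new = objective(eta_new, y, d_new, lambda);
      if (obj_new > obj + 1e-14) {
        double t = 1.0;
        int halvings = 0;
        arma::vec d_try, eta_try;
        double b0_try, obj_try = obj_new;
        while (obj_try > obj + 1e-14 && halvings < 50) {
          t *= 0.5;
          d_try = delta + t * (d_new - delta);
          b0_try = b0 + t * (b0_new - b0);
          eta_try = b0_try + X * d_try + offset;
          obj_try = objective(eta_try, y, d_try, lambda);
          ++halvings;
        }
        if (obj_try > obj) { // no descent possible: stationary
          inner_converged = true;
          break;
        }
        d_new = d_try; b0_new = b0_try; eta_new = eta_try; obj_new = obj_try;
      }
      delta = d_new;
      b0 = b0_new;
      eta = eta_new;
      double drop = obj - obj_new;
      obj = obj_new;
      trace.push_back(obj);
      if (drop < tol * std::max(1.0, std::fabs(obj))) {
        inner_converged = true;
        ++total_outer;
        break;
      }
    }
    if (!inner_converged) break; // outer budget exhausted
    // KKT check over the screened-out coordinates
    arma::vec g = full_gradient(X, y, eta);
    bool violation = false;
    for (arma::uword j = 0; j < p; ++j) {
      if (!in_set[j] && std::fabs(g(j)) > lambda * (1.0 + 1e-9) + 1e-12) {
        in_set[j] = true;
        coords.push_back(j);
        violation = true;
      }
    }
    if (!violation) {
      converged = true;
      break;
    }
  }

  return List::create(_["b0"] = b0, _["delta"] = delta,
                      _["objective"] = obj,
                      _["trace"] = NumericVector(trace.begin(), trace.end()),
                      _["converged"] = converged);
}

// Warm-started path over a decreasing lambda grid.
// Returns (p+1) x L matrix: row 0 = intercept, rows 1..p = delta.
// Stops early (repeating the last solution) once the fit is essentially
// saturated (99.9% of the null deviance explained).
// [[Rcpp::export(name = ".cd_lasso_path")]]
arma::mat cd_lasso_path(const arma::mat& X, const arma::vec& y,
                        const arma::vec& lambdas, const arma::vec& offset,
                        double tol = 1e-8, int max_outer = 500) {
  const arma::uword p = X.n_cols, L = lambdas.n_elem;
  arma::mat out(p + 1, L);
  arma::vec delta(p, arma::fill::zeros);
  // intercept-only start
  double ybar = arma::mean(y);
  if (ybar < 1e-12) ybar = 1e-12;
  if (ybar > 1 - 1e-12) ybar = 1 - 1e-12;
  double b0 = std::log(ybar / (1.0 - ybar)) - arma::mean(offset);
  double nll0 = -1.0, prev_nll = -1.0;
  int flat = 0;
  for (arma::uword l = 0; l < L; ++l) {
    List fit = cd_lasso_logistic(X, y, lambdas(l), offset, delta, b0,
                                 tol, max_outer, 25);
    b0 = as<double>(fit["b0"]);
    delta = as<arma::vec>(fit["delta"]);
    out(0, l) = b0;
    out.submat(1, l, p, l) = delta;
    double nll = as<double>(fit["objective"]) -
      lambdas(l) * arma::accu(arma::abs(delta));
    if (l == 0) {
      nll0 = std::max(nll, 1e-12);
    } else if (nll < nll0 * (1.0 - 1e-4)) {
      if (prev_nll - nll < 1e-5 * nll0) ++flat; else flat = 0;
    }
    prev_nll = nll;
    // saturated or flat fit: keep the last solution for the rest
    if ((nll <= 1e-3 * nll0 || flat >= 3) && l + 1 < L) {
      for (arma::uword k = l + 1; k < L; ++k) out.col(k) = out.col(l);
      break;
    }
  }
  return out;
}

// Fit a warm-started path on training data and score each lambda on a
// held-out fold, stopping early once the held-out loss is clearly past
// its minimum (or the training fit saturates).  Lambdas cut off by the
// stop keep the last computed held-out loss, which can never become the
// arg-min, so early stopping does not change the selected penalty.
// [[Rcpp::export(name = ".cd_cv_fold")]]
arma::vec cd_cv_fold(const arma::mat& Xtr, const arma::vec& ytr,
                     const arma::mat& Xte, const arma::vec& yte,
                     const arma::vec& lambdas, const arma::vec& offtr,
                     const arma::vec& offte,
                     double tol = 1e-5, int max_outer = 500) {
  const arma::uword p = Xtr.n_cols, L = lambdas.n_elem;
  const arma::uword nte = Xte.n_rows;
  arma::vec out(L);
  arma::vec delta(p, arma::fill::zeros);
  double ybar = arma::mean(ytr);
  if (ybar < 1e-12) ybar = 1e-12;
  if (ybar > 1 - 1e-12) ybar = 1 - 1e-12;
  double b0 = std::log(ybar / (1.0 - ybar)) - arma::mean(offtr);
  double nll0 = -1.0, prev_nll = -1.0;
  int flat = 0;
  double best_te = arma::datum::inf;
  arma::uword best_l = 0;
  for (arma::uword l = 0; l < L; ++l) {
    List fit = cd_lasso_logistic(Xtr, ytr, lambdas(l), offtr, delta, b0,
                                 tol, std::min(max_outer, 12), 15);
    b0 = as<double>(fit["b0"]);
    delta = as<arma::vec>(fit["delta"]);
    arma::vec eta = b0 + Xte * delta + offte;
    double te = 0.0;
    for (arma::uword i = 0; i < nte; ++i)
      te += log1pexp_stable(eta(i)) - yte(i) * eta(i);
    te /= static_cast<double>(nte);
    out(l) = te;
    if (te < best_te) { best_te = te; best_l = l; }
    double nll = as<double>(fit["objective"]) -
      lambdas(l) * arma::accu(arma::abs(delta));
    if (l == 0) {
      nll0 = std::max(nll, 1e-12);
    } else if (nll < nll0 * (1.0 - 1e-4)) {
      // flat detection only once the fit has started to improve —
      // the all-zero prefix of the path is flat by construction
      if (prev_nll - nll < 1e-5 * nll0) ++flat; else flat = 0;
    }
    prev_nll = nll;
    bool saturated = (nll <= 1e-3 * nll0 || flat >= 3);
    bool past_min = (l >= best_l + 10 && te > 1.02 * best_te + 1e-4);
    if ((saturated || past_min) && l + 1 < L) {
      for (arma::uword k = l + 1; k < L; ++k) out(k) = te;
      break;
    }
  }
  return out;
}

// Mean held-out negative log-likelihood for each column of a path fit.
// [[Rcpp::export(name = ".path_nll")]]
arma::vec path_nll(const arma::mat& coefs, const arma::mat& X,
                   const arma::vec& y, const arma::vec& offset) {
  const arma::uword L = coefs.n_cols, n = X.n_rows, p = X.n_cols;
  arma::vec out(L);
  for (arma::uword l = 0; l < L; ++l) {
    double b0 = coefs(0, l);
    arma::vec delta = coefs.submat(1, l, p, l);
    arma::vec eta = b0 + X * delta + offset;
    double nll = 0.0;
    for (arma::uword i = 0; i < n; ++i) {
      nll += log1pexp_stable(eta(i)) - y(i) * eta(i);
    }
    out(l) = nll / static_cast<double>(n);
  }
  return out;
}
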