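#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Accelerated iterative shrinkage-thresholding for the batch problem
//   min_S 0.5 * ||A S - X||_F^2 + lambda * ||S||_1,   optionally S >= 0.
// A is 2 x M with unit-norm columns, X is 2 x K; all K columns are solved
// simultaneously. Step size 1/L with L the largest eigenvalue of A'A.
// Momentum iterations may be non-monotone; if the objective rises for 10
// consecutive iterations the momentum is restarted (monotone fallback).

static double objective(const arma::mat& A, const arma::mat& S,
                        const arma::mat& X, double lambda) {
  arma::mat R = A * S - X;
  return 0.5 * arma::accu(arma::square(R)) + lambda * arma::accu(arma::abs(S));
}

// [[Rcpp::export]]
Rcpp::List ist_solve_cpp(const arma::mat& A, const arma::mat& X, double lambda,
                         bool nonneg, int max_iter, double tol,
                         double hard_zero_tol) {
  const arma::uword M = A.n_cols, K = X.n_cols;
  arma::mat AtA = A.t() * A;
  arma::mat AtX = A.t() * X;
  double L = arma::eig_sym(AtA).max();
  if (!(L > 0.0)) L = 1.0;
  const double step = 1.0 / L;
  const double thr = lambda / L;

  arma::mat S(M, K, arma::fill::zeros);
  arma::mat S_old = S, Y = S;
  double t = 1.0;
  double obj_old = objective(A, S, X, lambda);
  int iter = 0, rises = 0;

  for (iter = 1; iter <= max_iter; ++iter) {
    arma::mat Z = Y - step * (AtA * Y - AtX);
    if (nonneg) {
      S = Z - thr;               // one-sided shrink, then project onto S >= 0
      S.elem(arma::find(S < 0.0)).zeros();
    } else {
      S = arma::sign(Z) % arma::clamp(arma::abs(Z) - thr, 0.0, arma::datum::inf);
    }

    double obj = objective(A, S, X, lambda);
    if (!std::isfinite(obj))
      Rcpp::stop("IST solver diverged: non-finite objective at iteration %d", iter);

    if (obj > obj_old) {
      if (++rises >= 10) {       // monotone fallback: drop momentum
        t = 1.0;
        Y = S;
        rises = 0;
      }
    } else {
      rises = 0;
    }

    double denom = std::max(std::abs(obj_old), 1e-12);
    bool converged = std::abs(obj - obj_old) / denom < tol;

    double t_new = 0.5 * (1.0 + std::sqrt(1.0 + 4.0 * t * t));
    Y = S + ((t - 1.0) / t_new) * (S - S_old);
    S_old = S;
    t = t_new;
    obj_old = obj;
    if (converged) break;
  }

  if (hard_zero_tol > 0.0)
    S.elem(arma::find(arma::abs(S) < hard_zero_tol)).zeros();
  double obj_final = objective(A, S, X, lambda);

  return Rcpp::List::create(Rcpp::Named("S") = S,
                            Rcpp::Named("objective") = obj_final,
                            Rcpp::Named("iterations_run") = std::min(iter, max_iter));
}
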