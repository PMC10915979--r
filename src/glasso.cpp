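// Graphical lasso: L1-penalised Gaussian precision estimation by block
// coordinate descent (Friedman-style), with the penalty on off-diagonal
// precision entries only.  Small fixed dimension (C ~ 10) is the target
// regime: one fit per sliding window, many thousands of fits per cohort.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double soft(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// Lasso sub-problem for one column: minimise
//   0.5 * b' W11 b - s12' b + lambda * ||b||_1
// by cyclic coordinate descent, warm-started at b.
static void lasso_cd(const mat& W11, const vec& s12, double lambda,
                     vec& b, double tol, int max_sweep) {
  const uword p = s12.n_elem;
  for (int sweep = 0; sweep < max_sweep; ++sweep) {
    double delta = 0.0;
    for (uword l = 0; l < p; ++l) {
      double grad = s12(l) - dot(W11.col(l), b) + W11(l, l) * b(l);
      double bl = soft(grad, lambda) / W11(l, l);
      delta = std::max(delta, std::abs(bl - b(l)));
      b(l) = bl;
    }
    if (delta < tol) break;
  }
}

// [[Rcpp::export(name = ".glasso_cd")]]
Rcpp::List glasso_cd(const arma::mat& S, double lambda,
                     double tol = 1e-7, int max_iter = 200) {
  const uword p = S.n_rows;
  if (S.n_cols != p) Rcpp::stop("covariance matrix must be square");
  if (lambda < 0) Rcpp::stop("lambda must be >= 0");

  mat W = S;                 // working covariance estimate; diagonal fixed at S
  mat B(p - 1, p, fill::zeros);
  double off_scale = 0.0;
  for (uword i = 0; i < p; ++i)
    for (uword j = 0; j < p; ++j)
      if (i != j) off_scale += std::abs(S(i, j));
  off_scale = std::max(off_scale / std::max(1.0, double(p * (p - 1))), 1e-12);

  uvec all = regspace<uvec>(0, p - 1);
  bool converged = false;
  int it = 0;
  const double thresh = tol * off_scale;
  for (it = 0; it < max_iter; ++it) {
    double sum_change = 0.0;
    for (uword j = 0; j < p; ++j) {
      uvec idx = find(all != j);
      mat W11 = W.submat(idx, idx);
      vec s12 = S.col(j);
      s12 = s12.elem(idx);
      vec b = B.col(j);
      lasso_cd(W11, s12, lambda, b, 0.05 * thresh, 1000);
      B.col(j) = b;
      vec w12 = W11 * b;
      for (uword r = 0; r < idx.n_elem; ++r) {
        sum_change += std::abs(W(idx(r), j) - w12(r));
        W(idx(r), j) = w12(r);
        W(j, idx(r)) = w12(r);
      }
    }
    if (sum_change / double(p * (p - 1)) < thresh) { converged = true; ++it; break; }
  }

  // Recover the precision matrix from the final column solutions; this
  // preserves exact zeros produced by the soft threshold.
  mat Theta(p, p, fill::zeros);
  for (uword j = 0; j < p; ++j) {
    uvec idx = find(all != j);
    vec b = B.col(j);
    vec w12 = W.col(j);
    w12 = w12.elem(idx);
    double denom = W(j, j) - dot(w12, b);
    if (denom <= 0) Rcpp::stop("graphical lasso lost positive definiteness");
    double tjj = 1.0 / denom;
    Theta(j, j) = tjj;
    for (uword r = 0; r < idx.n_elem; ++r) Theta(idx(r), j) = -b(r) * tjj;
  }
  Theta = 0.5 * (Theta + Theta.t());

  return Rcpp::List::create(
    Rcpp::Named("precision") = Theta,
    Rcpp::Named("covariance") = W,
    Rcpp::Named("iterations") = it,
    Rcpp::Named("converged") = converged);
}
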