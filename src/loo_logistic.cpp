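// Fast path for the exhaustive leave-one-out panel search: thousands of small
// class-balanced ridge logistic fits. Mirrors fit_balanced_logistic() /
// .loo_probs_r() in R/ exactly (Newton with step halving, unpenalized
// intercept, training-fold autoscaling); equivalence is enforced by tests.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static double objective(const mat& Xd, const vec& y, const vec& s,
                        const vec& pen, const vec& beta) {
  vec eta = Xd * beta;
  double ll = 0.0;
  for (uword i = 0; i < eta.n_elem; ++i) {
    double e = eta(i);
    double v = (e > 0) ? e * (1.0 - y(i)) + std::log1p(std::exp(-e))
                       : -y(i) * e + std::log1p(std::exp(e));
    ll += s(i) * v;
  }
  return ll + 0.5 * dot(pen, beta % beta);
}

// Newton fit; beta holds the warm start and receives the solution.
static void newton_fit(const mat& Xd, const vec& y, const vec& s,
                       const vec& pen, vec& beta,
                       int max_iter = 100, double tol = 1e-10) {
  double f = objective(Xd, y, s, pen, beta);
  for (int it = 0; it < max_iter; ++it) {
    vec eta = Xd * beta;
    vec mu = 1.0 / (1.0 + exp(-eta));
    vec grad = Xd.t() * (s % (mu - y)) + pen % beta;
    vec w = s % mu % (1.0 - mu);
    w.transform([](double v) { return std::max(v, 1e-12); });
    mat H = Xd.t() * (Xd.each_col() % w);
    H.diag() += pen;
    vec step = solve(H, grad, solve_opts::fast);
    double alpha = 1.0, f_new = f;
    vec beta_new = beta;
    while (true) {
      beta_new = beta - alpha * step;
      f_new = objective(Xd, y, s, pen, beta_new);
      if (f_new <= f + 1e-12 || alpha < 1e-8) break;
      alpha *= 0.5;
    }
    double delta = f - f_new;
    beta = beta_new;
    f = f_new;
    if (std::fabs(delta) < tol * (std::fabs(f) + 1.0)) break;
  }
}

// [[Rcpp::export]]
arma::mat cpp_loo_panel_probs(const arma::mat& X, const arma::ivec& y,
                              Rcpp::List panels, double lambda = 1.0,
                              bool balanced = true) {
  const uword n = X.n_rows;
  vec yv = conv_to<vec>::from(y);
  mat out(n, panels.size());

  for (int pi = 0; pi < panels.size(); ++pi) {
    uvec cols = Rcpp::as<uvec>(panels[pi]);  // 0-based column indices
    mat Xp = X.cols(cols);
    const uword p = Xp.n_cols;
    vec pen(p + 1, fill::value(lambda));
    pen(0) = 0.0;  // intercept unpenalized

    for (uword i = 0; i < n; ++i) {
      // training fold = all rows but i
      uvec tr(n - 1);
      uword k = 0;
      for (uword r = 0; r < n; ++r) if (r != i) tr(k++) = r;
      mat Xtr = Xp.rows(tr);
      vec ytr = yv.elem(tr);

      rowvec ctr = mean(Xtr, 0);
      rowvec scl = stddev(Xtr, 0, 0);  // sample SD (n-1), as in R
      scl.transform([](double v) { return v == 0.0 ? 1.0 : v; });
      Xtr.each_row() -= ctr;
      Xtr.each_row() /= scl;

      double n_tr = static_cast<double>(n - 1);
      double n_pos = accu(ytr);
      double n_neg = n_tr - n_pos;
      if (n_pos == 0 || n_neg == 0)
        Rcpp::stop("single-class training fold");
      vec s(n - 1, fill::ones);
      if (balanced)
        for (uword r = 0; r < n - 1; ++r)
          s(r) = (ytr(r) == 1.0) ? n_tr / (2.0 * n_pos) : n_tr / (2.0 * n_neg);

      mat Xd = join_rows(ones<vec>(n - 1), Xtr);
      vec beta(p + 1, fill::zeros);
      newton_fit(Xd, ytr, s, pen, beta);

      rowvec xt = (Xp.row(i) - ctr) / scl;
      double eta = beta(0) + dot(xt, beta.subvec(1, p));
      out(i, pi) = 1.0 / (1.0 + std::exp(-eta));
    }
  }
  return out;
}
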