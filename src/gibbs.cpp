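#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Gibbs sampler for the conjugate normal linear model
//   y = X beta + eps,  eps ~ N(0, sigma2 I)
// with independent normal priors beta_j ~ N(prior_mean_j, prior_sd_j^2)
// and sigma2 ~ Inverse-Gamma(shape0, rate0).
//
// Full conditionals (both exact):
//   beta | sigma2, y ~ N(m, V),  V = (X'X/sigma2 + P)^-1,
//                                m = V (X'y/sigma2 + P p0)
//   sigma2 | beta, y ~ IG(shape0 + n/2, rate0 + RSS(beta)/2)
// where P = diag(1/prior_sd^2) and p0 = prior_mean.
//
// Uses R's RNG so set.seed() on the R side makes runs reproducible.
// Returns the retained draws, one row per draw: (beta..., sigma).

// [[Rcpp::export(name = ".gibbs_conjugate_lm")]]
arma::mat gibbs_conjugate_lm(const arma::vec& y,
                             const arma::mat& X,
                             const arma::vec& prior_mean,
                             const arma::vec& prior_sd,
                             double shape0,
                             double rate0,
                             int n_iter,
                             int burn_in,
                             int thin,
                             const arma::vec& beta_init,
                             double sigma2_init) {
  const int n = X.n_rows;
  const int p = X.n_cols;
  if ((int) y.n_elem != n) stop("length(y) must match nrow(X)");
  if ((int) prior_mean.n_elem != p || (int) prior_sd.n_elem != p)
    stop("prior vectors must have one entry per coefficient");
  if (n_iter <= burn_in) stop("n_iter must exceed burn_in");
  if (thin < 1) stop("thin must be >= 1");

  const arma::mat XtX = X.t() * X;
  const arma::vec Xty = X.t() * y;
  const arma::vec prior_prec = 1.0 / arma::square(prior_sd);
  const arma::mat P = arma::diagmat(prior_prec);
  const arma::vec Pm = prior_prec % prior_mean;

  arma::vec beta = beta_init;
  double sigma2 = sigma2_init;

  const int n_keep = (n_iter - burn_in + thin - 1) / thin;
  arma::mat out(n_keep, p + 1);

  RNGScope scope;
  int kept = 0;
  for (int it = 0; it < n_iter; ++it) {
    // beta | sigma2
    arma::mat prec = XtX / sigma2 + P;
    arma::mat R_chol = arma::chol(prec);  // upper triangular, prec = R'R
    arma::vec m = arma::solve(prec, Xty / sigma2 + Pm,
                              arma::solve_opts::likely_sympd);
    arma::vec z(p);
    for (int j = 0; j < p; ++j) z(j) = norm_rand();
    beta = m + arma::solve(arma::trimatu(R_chol), z);

    // sigma2 | beta
    arma::vec resid = y - X * beta;
    double shape = shape0 + 0.5 * n;
    double rate = rate0 + 0.5 * arma::dot(resid, resid);
    sigma2 = rate / R::rgamma(shape, 1.0);  // 1/Gamma(shape, rate)

    if (it >= burn_in && (it - burn_in) % thin == 0) {
      for (int j = 0; j < p; ++j) out(kept, j) = beta(j);
      out(kept, p) = std::sqrt(sigma2);
      ++kept;
    }
  }
  return out;
}
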