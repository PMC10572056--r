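// Gibbs samplers for Bayesian ridge-regression (SNP-BLUP) genomic prediction.
// All randomness goes through R's RNG so seeded runs are bit-reproducible
// from set.seed(); the draw order inside each iteration is fixed.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Draw Sigma ~ InvWishart(df, S) (density ∝ |Sigma|^-(df+t+1)/2 exp(-tr(S Sigma^-1)/2))
// via the Bartlett decomposition of Wishart(df, S^-1).
static arma::mat rinvwishart(double df, const arma::mat &S) {
  const int t = S.n_rows;
  arma::mat L = arma::chol(arma::inv_sympd(S), "lower");
  arma::mat A(t, t, arma::fill::zeros);
  for (int i = 0; i < t; ++i) {
    A(i, i) = std::sqrt(R::rchisq(df - i));
    for (int j = 0; j < i; ++j) A(i, j) = R::norm_rand();
  }
  arma::mat LA = L * A;
  return arma::inv_sympd(arma::symmatu(LA * LA.t()));
}

static arma::vec rnorm_vec(int n) {
  arma::vec z(n);
  for (int i = 0; i < n; ++i) z(i) = R::norm_rand();
  return z;
}

static arma::mat rnorm_mat(int r, int c) {
  arma::mat z(r, c);
  // column-major to keep the RNG stream layout-stable
  for (int j = 0; j < c; ++j)
    for (int i = 0; i < r; ++i) z(i, j) = R::norm_rand();
  return z;
}

// Scaled-inverse-chi-square full conditional: (nu*S + ss) / chisq(nu + n)
static double rscinv_chisq(double nu, double S, double ss, double n) {
  return (nu * S + ss) / R::rchisq(nu + n);
}

// [[Rcpp::export]]
List gibbs_st_cpp(const arma::vec &y, const arma::mat &X, const arma::mat &W,
                  const arma::mat &M, int n_iter, int burn_in, int thin,
                  double nu_a, double nu_d, double nu_e,
                  double S_a, double S_d, double S_e,
                  double sigma2_a, double sigma2_d, double sigma2_e,
                  bool fix_variances) {
  const int n = y.n_elem, f = X.n_cols, L = W.n_cols, p = M.n_cols;
  const int n_keep = (n_iter - burn_in) / thin;
  if (n_keep <= 0) stop("no retained draws: check n_iter/burn_in/thin");

  arma::mat XtX = X.t() * X;
  arma::mat Lxx = arma::chol(arma::inv_sympd(XtX), "lower");
  arma::vec mtm = arma::sum(arma::square(M), 0).t();
  arma::vec wtw = L > 0 ? arma::sum(arma::square(W), 0).t() : arma::vec();

  arma::vec b(f, arma::fill::zeros), d(L, arma::fill::zeros),
      alpha(p, arma::fill::zeros);
  arma::vec e = y;  // residual given current (zero) effects

  arma::mat keep_alpha(n_keep, p), keep_b(n_keep, f), keep_d(n_keep, std::max(L, 0));
  arma::vec keep_sa(n_keep), keep_sd(n_keep), keep_se(n_keep);

  int kept = 0;
  for (int it = 1; it <= n_iter; ++it) {
    // fixed effects, flat prior: joint multivariate-normal update
    e += X * b;
    arma::vec bmean = arma::solve(XtX, X.t() * e, arma::solve_opts::likely_sympd);
    b = bmean + std::sqrt(sigma2_e) * (Lxx * rnorm_vec(f));
    e -= X * b;

    // DIM class effects, iid N(0, sigma2_d)
    for (int l = 0; l < L; ++l) {
      double old = d(l);
      double rhs = arma::dot(W.col(l), e) + wtw(l) * old;
      double prec = wtw(l) / sigma2_e + 1.0 / sigma2_d;
      double mean = (rhs / sigma2_e) / prec;
      double dl = mean + R::norm_rand() / std::sqrt(prec);
      d(l) = dl;
      e -= W.col(l) * (dl - old);
    }

    // marker effects, single-site updates
    double lambda = sigma2_e / sigma2_a;
    for (int j = 0; j < p; ++j) {
      double old = alpha(j);
      double rhs = arma::dot(M.col(j), e) + mtm(j) * old;
      double C = mtm(j) + lambda;
      double aj = rhs / C + R::norm_rand() * std::sqrt(sigma2_e / C);
      alpha(j) = aj;
      e -= M.col(j) * (aj - old);
    }

    if (!fix_variances) {
      sigma2_a = rscinv_chisq(nu_a, S_a, arma::dot(alpha, alpha), p);
      if (L > 0) sigma2_d = rscinv_chisq(nu_d, S_d, arma::dot(d, d), L);
      sigma2_e = rscinv_chisq(nu_e, S_e, arma::dot(e, e), n);
    }
    if (!e.is_finite())
      stop("non-finite residual at iteration %d", it);

    if (it > burn_in && (it - burn_in) % thin == 0 && kept < n_keep) {
      keep_alpha.row(kept) = alpha.t();
      keep_b.row(kept) = b.t();
      if (L > 0) keep_d.row(kept) = d.t();
      keep_sa(kept) = sigma2_a;
      keep_sd(kept) = sigma2_d;
      keep_se(kept) = sigma2_e;
      ++kept;
    }
  }

  return List::create(_["alpha"] = keep_alpha, _["b"] = keep_b, _["d"] = keep_d,
                      _["sigma2_a"] = keep_sa, _["sigma2_d"] = keep_sd,
                      _["sigma2_e"] = keep_se, _["n_kept"] = kept);
}

// [[Rcpp::export]]
List gibbs_mt_cpp(const arma::mat &Y, const arma::mat &X, const arma::mat &W,
                  const arma::mat &M, int n_iter, int burn_in, int thin,
                  double nu_a, double nu_d, double nu_e,
                  const arma::mat &S_a, const arma::vec &S_d, const arma::mat &S_e,
                  arma::mat Sigma_a, arma::vec sigma2_d, arma::mat R_mat,
                  bool fix_variances) {
  const int n = Y.n_rows, t = Y.n_cols, f = X.n_cols, L = W.n_cols,
            p = M.n_cols;
  const int n_keep = (n_iter - burn_in) / thin;
  if (n_keep <= 0) stop("no retained draws: check n_iter/burn_in/thin");

  arma::mat XtX = X.t() * X;
  arma::mat Lxx = arma::chol(arma::inv_sympd(XtX), "lower");
  arma::vec mtm = arma::sum(arma::square(M), 0).t();
  arma::vec wtw = L > 0 ? arma::sum(arma::square(W), 0).t() : arma::vec();

  arma::mat B(f, t, arma::fill::zeros), D(L > 0 ? L : 0, t, arma::fill::zeros),
      A(p, t, arma::fill::zeros);
  arma::mat E = Y;

  arma::cube keep_A(p, t, n_keep), keep_B(f, t, n_keep),
      keep_D(std::max(L, 1), t, n_keep, arma::fill::zeros),
      keep_Sa(t, t, n_keep), keep_R(t, t, n_keep);
  arma::mat keep_sd(n_keep, t);

  int kept = 0;
  for (int it = 1; it <= n_iter; ++it) {
    arma::mat Rinv = arma::inv_sympd(arma::symmatu(R_mat));
    arma::mat Sainv = arma::inv_sympd(arma::symmatu(Sigma_a));
    arma::mat LR = arma::chol(arma::symmatu(R_mat), "lower");

    // fixed effects: matrix-normal full conditional, mean independent of R
    E += X * B;
    arma::mat Bmean = arma::solve(XtX, X.t() * E, arma::solve_opts::likely_sympd);
    B = Bmean + Lxx * rnorm_mat(f, t) * LR.t();
    E -= X * B;

    // DIM class effects: diagonal covariance across traits, coupled via R
    for (int l = 0; l < L; ++l) {
      arma::vec old = D.row(l).t();
      arma::vec rhs = E.t() * W.col(l) + wtw(l) * old;
      arma::mat Prec = wtw(l) * Rinv + arma::diagmat(1.0 / sigma2_d);
      arma::mat Lp = arma::chol(arma::symmatu(Prec), "lower");
      arma::vec mean = arma::solve(Prec, Rinv * rhs, arma::solve_opts::likely_sympd);
      arma::vec dl = mean + arma::solve(arma::trimatu(Lp.t()), rnorm_vec(t));
      D.row(l) = dl.t();
      E -= W.col(l) * (dl - old).t();
    }

    // per-marker effect vectors across traits
    for (int j = 0; j < p; ++j) {
      arma::vec old = A.row(j).t();
      arma::vec rhs = E.t() * M.col(j) + mtm(j) * old;
      arma::mat Prec = mtm(j) * Rinv + Sainv;
      arma::mat Lp = arma::chol(arma::symmatu(Prec), "lower");
      arma::vec mean = arma::solve(Prec, Rinv * rhs, arma::solve_opts::likely_sympd);
      arma::vec aj = mean + arma::solve(arma::trimatu(Lp.t()), rnorm_vec(t));
      A.row(j) = aj.t();
      E -= M.col(j) * (aj - old).t();
    }

    if (!fix_variances) {
      Sigma_a = rinvwishart(nu_a + p, arma::symmatu(S_a + A.t() * A));
      if (L > 0)
        for (int k = 0; k < t; ++k)
          sigma2_d(k) = rscinv_chisq(nu_d, S_d(k),
                                     arma::dot(D.col(k), D.col(k)), L);
      R_mat = rinvwishart(nu_e + n, arma::symmatu(S_e + E.t() * E));
    }
    if (!E.is_finite())
      stop("non-finite residual at iteration %d", it);

    if (it > burn_in && (it - burn_in) % thin == 0 && kept < n_keep) {
      keep_A.slice(kept) = A;
      keep_B.slice(kept) = B;
      if (L > 0) keep_D.slice(kept).rows(0, L - 1) = D;
      keep_Sa.slice(kept) = Sigma_a;
      keep_R.slice(kept) = R_mat;
      keep_sd.row(kept) = sigma2_d.t();
      ++kept;
    }
  }

  return List::create(_["alpha"] = keep_A, _["b"] = keep_B, _["d"] = keep_D,
                      _["Sigma_a"] = keep_Sa, _["R"] = keep_R,
                      _["sigma2_d"] = keep_sd, _["n_kept"] = kept);
}
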