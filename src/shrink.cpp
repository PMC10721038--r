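#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// log N(x; 0, Sigma), Sigma SPD (guaranteed: prior PSD + positive diagonal noise)
static double dmvnorm0_log(const vec& x, const mat& Sigma) {
  mat L;
  if (!chol(L, Sigma, "lower")) {
    // fall back to eigen decomposition for numerically borderline matrices
    vec ev; mat Q;
    eig_sym(ev, Q, Sigma);
    ev = clamp(ev, 1e-12, datum::inf);
    vec z = Q.t() * x;
    return -0.5 * (x.n_elem * std::log(2.0 * datum::pi) + accu(log(ev)) +
                   accu(square(z) / ev));
  }
  vec z = solve(trimatl(L), x);
  return -0.5 * (x.n_elem * std::log(2.0 * datum::pi) +
                 2.0 * accu(log(L.diag())) + dot(z, z));
}

// Marginal log-likelihood matrix: entry (j, c) = log N(Bhat_j; 0, U_c + diag(Shat_j^2)).
// [[Rcpp::export]]
arma::mat mix_loglik(const arma::mat& Bhat, const arma::mat& Shat,
                     const arma::cube& Ucube) {
  const uword J = Bhat.n_rows, C = Ucube.n_slices;
  mat out(J, C);
  for (uword j = 0; j < J; ++j) {
    vec b = Bhat.row(j).t();
    vec s2 = square(Shat.row(j).t());
    for (uword c = 0; c < C; ++c) {
      mat Sigma = Ucube.slice(c);
      Sigma.diag() += s2;
      out(j, c) = dmvnorm0_log(b, Sigma);
    }
  }
  return out;
}

static vec responsibilities(const vec& b, const vec& s2, const cube& Ucube,
                            const vec& prior_pi) {
  const uword C = Ucube.n_slices;
  vec ll(C);
  for (uword c = 0; c < C; ++c) {
    mat Sigma = Ucube.slice(c);
    Sigma.diag() += s2;
    ll(c) = dmvnorm0_log(b, Sigma);
  }
  vec w(C, fill::zeros);
  double m = ll.max();
  for (uword c = 0; c < C; ++c)
    if (prior_pi(c) > 0) w(c) = prior_pi(c) * std::exp(ll(c) - m);
  return w / accu(w);
}

// Posterior mixture moments under prior sum_c pi_c N(0, U_c) and noise diag(Shat_j^2):
// responsibilities, overall posterior mean and posterior SD (law of total variance).
// [[Rcpp::export]]
Rcpp::List mix_posterior(const arma::mat& Bhat, const arma::mat& Shat,
                         const arma::cube& Ucube, const arma::vec& prior_pi) {
  const uword J = Bhat.n_rows, R = Bhat.n_cols, C = Ucube.n_slices;
  mat pmean(J, R), psd(J, R), resp(J, C);
  for (uword j = 0; j < J; ++j) {
    vec b = Bhat.row(j).t();
    vec s2 = square(Shat.row(j).t());
    vec w = responsibilities(b, s2, Ucube, prior_pi);
    resp.row(j) = w.t();
    vec m(R, fill::zeros);
    mat second(R, R, fill::zeros);
    for (uword c = 0; c < C; ++c) {
      if (w(c) <= 0) continue;
      const mat& U = Ucube.slice(c);
      mat SV = U;
      SV.diag() += s2;
      mat A = solve(SV, U);          // (U + V)^{-1} U
      vec mu = A.t() * b;            // U (U + V)^{-1} b
      mat P = U - U * A;             // posterior covariance for component c
      m += w(c) * mu;
      second += w(c) * (P + mu * mu.t());
    }
    mat Cov = second - m * m.t();
    pmean.row(j) = m.t();
    psd.row(j) = sqrt(clamp(Cov.diag(), 0.0, datum::inf)).t();
  }
  return Rcpp::List::create(Rcpp::Named("mean") = pmean,
                            Rcpp::Named("sd") = psd,
                            Rcpp::Named("responsibilities") = resp);
}

// Posterior draws: per feature and draw, sample a mixture component by its
// responsibility, then a multivariate normal from that component's posterior.
// Uses R's RNG so set.seed() controls reproducibility. Returns J x R x n_draws.
// [[Rcpp::export]]
arma::cube mix_draws(const arma::mat& Bhat, const arma::mat& Shat,
                     const arma::cube& Ucube, const arma::vec& prior_pi,
                     const int n_draws) {
  const uword J = Bhat.n_rows, R = Bhat.n_cols, C = Ucube.n_slices;
  if (n_draws < 1) Rcpp::stop("n_draws must be >= 1");
  Rcpp::RNGScope scope;
  cube out(J, R, (uword)n_draws);
  for (uword j = 0; j < J; ++j) {
    vec b = Bhat.row(j).t();
    vec s2 = square(Shat.row(j).t());
    vec w = responsibilities(b, s2, Ucube, prior_pi);
    vec cw = cumsum(w);
    std::vector<bool> ready(C, false);
    std::vector<vec> mu(C);
    std::vector<mat> fac(C);
    for (int d = 0; d < n_draws; ++d) {
      double u = R::unif_rand();
      uword c = 0;
      while (c + 1 < C && u > cw(c)) ++c;
      if (!ready[c]) {
        const mat& U = Ucube.slice(c);
        mat SV = U;
        SV.diag() += s2;
        mat A = solve(SV, U);
        mu[c] = A.t() * b;
        mat P = symmatu(U - U * A);
        vec ev; mat Q;
        eig_sym(ev, Q, P);
        ev = clamp(ev, 0.0, datum::inf);
        fac[c] = Q * diagmat(sqrt(ev));
        ready[c] = true;
      }
      vec z(R);
      for (uword r = 0; r < R; ++r) z(r) = R::norm_rand();
      vec x = mu[c] + fac[c] * z;
      for (uword r = 0; r < R; ++r) out(j, r, (uword)d) = x(r);
    }
  }
  return out;
}
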