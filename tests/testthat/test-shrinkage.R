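test_that("strong-signal selection ranks by max |z| with stable ties", {
  Bhat <- matrix(0, 10, 3); Shat <- matrix(1, 10, 3)
  Bhat[7, ] <- 10
  expect_identical(select_strong_signals(Bhat, Shat)[1], 7L)
  # all identical: selection = first max_features in input order
  B2 <- matrix(1, 10, 3); S2 <- matrix(1, 10, 3)
  expect_warning(sel <- select_strong_signals(B2, S2, z_min = 4,
                                              max_features = 4), "falling back")
  expect_identical(sel, 1:4)
})

test_that("planted strong features are found among 900 nulls", {
  set.seed(8)
  J <- 1000; R <- 4
  Shat <- matrix(0.1, J, R)
  Bhat <- matrix(rnorm(J * R, sd = 0.1), J, R)
  planted <- sample(J, 100)
  Bhat[planted, 1] <- Bhat[planted, 1] + 0.8 * sign(rnorm(100))  # z ~ 8
  sel <- select_strong_signals(Bhat, Shat, z_min = 4, max_features = 100)
  expect_gte(length(intersect(sel, planted)), 95)
})

test_that("data-driven covariances are PSD with unit spectral norm", {
  # rank-1 input: dominant component proportional to u u'
  u <- c(1, 2, -1) / sqrt(6)
  Z <- outer(rexp(30) + 0.5, u)
  U <- data_driven_covariances(Z, n_pcs = 2)
  expect_equal(U[["pca_1"]], tcrossprod(u), tolerance = 1e-8)
  set.seed(9)
  Zr <- matrix(rnorm(200 * 5), 200, 5)
  Ur <- data_driven_covariances(Zr, n_pcs = 3)
  for (u_c in Ur) {
    ev <- eigen(u_c, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-10)
    expect_equal(max(abs(ev)), 1, tolerance = 1e-10)
  }
  expect_error(data_driven_covariances(matrix(0, 10, 3), 2), "degenerate")
})

test_that("PCA covariances recover a planted rank-2 structure", {
  set.seed(10)
  v1 <- c(1, 0, 0, 0); v2 <- c(0, 1, 1, 0) / sqrt(2)
  Sigma <- 4 * tcrossprod(v1) + 2 * tcrossprod(v2) + 1e-4 * diag(4)
  Z <- matrix(rnorm(500 * 4), 500) %*% chol(Sigma)
  U <- data_driven_covariances(Z, n_pcs = 2)
  eg <- eigen(U[["pca_recon"]], symmetric = TRUE)
  ang <- function(a, b) acos(min(1, abs(sum(a * b)))) * 180 / pi
  expect_lt(ang(eg$vectors[, 1], v1), 10)
  expect_lt(ang(eg$vectors[, 2], v2), 10)
})

test_that("the scale grid is geometric with ratio sqrt(2), includes 0, spans the data", {
  Bhat <- matrix(c(0.2, -1.0), 2, 1)
  Shat <- matrix(c(0.1, 0.4), 2, 1)
  g <- build_scale_grid(Bhat, Shat)
  expect_identical(g[1], 0)
  pos <- g[-1]
  expect_equal(pos[1], 0.01)
  expect_gte(max(pos), 2.0)
  expect_equal(diff(log(pos)), rep(log(sqrt(2)), length(pos) - 1),
               tolerance = 1e-12)
  expect_true(all(diff(pos) > 0))
  # all-zero effects: degenerate two-point grid
  expect_equal(build_scale_grid(matrix(0, 2, 1), Shat), c(0, 0.01))
})

test_that("EM returns the degenerate simplex for a single component and is monotone", {
  set.seed(12)
  Bhat <- matrix(rnorm(50), 50, 1); Shat <- matrix(1, 50, 1)
  prior <- fit_mixture_weights(Bhat, Shat, U_list = list(), scales = 0)
  expect_equal(prior$pi, 1)
  # monotone non-decreasing log-likelihood on a random panel
  U <- list(a = diag(2), b = matrix(c(1, .9, .9, 1), 2))
  p2 <- fit_mixture_weights(matrix(rnorm(200), 100, 2),
                            matrix(0.5, 100, 2), U, c(0, 0.5, 1, 2))
  expect_true(all(diff(p2$loglik_trace) >= -1e-8))
  expect_equal(sum(p2$pi), 1)
  expect_true(all(p2$pi >= 0))
})

test_that("EM recovers a known null weight", {
  set.seed(13)
  J <- 5000; R <- 3
  U_true <- tcrossprod(c(1, 1, -1)) / 3  # spectral norm 1
  w_true <- 1.5
  is_sig <- runif(J) < 0.3
  B <- matrix(0, J, R)
  n_sig <- sum(is_sig)
  B[is_sig, ] <- matrix(rnorm(n_sig * R), n_sig) %*%
    chol(w_true^2 * U_true + 1e-10 * diag(R))
  Shat <- matrix(0.3, J, R)
  Bhat <- B + matrix(rnorm(J * R, sd = 0.3), J)
  prior <- fit_mixture_weights(Bhat, Shat, list(u = U_true),
                               scales = c(0, 0.75, 1.5, 3))
  expect_lt(abs(prior$pi[1] - 0.7), 0.05)
})

test_that("posterior means obey closed forms and the null contract", {
  I2 <- diag(2)
  prior <- make_prior(list(iso = I2), pi = c(0, 1))
  Bhat <- matrix(c(1, -2, 0.5, 0, 3, 1), 3, 2)
  Shat <- matrix(1, 3, 2)
  post <- compute_posteriors(Bhat, Shat, prior)
  expect_equal(post$mean, Bhat / 2, tolerance = 1e-12)
  # Bhat = 0 -> posterior mean 0
  post0 <- compute_posteriors(matrix(0, 2, 2), matrix(1, 2, 2), prior)
  expect_equal(post0$mean, matrix(0, 2, 2))
  # pure null prior -> mean 0, sd 0
  pnull <- make_prior(list(iso = I2), pi = c(1, 0))
  postn <- compute_posteriors(Bhat, Shat, pnull)
  expect_equal(postn$mean, 0 * Bhat)
  expect_equal(postn$sd, 0 * Bhat)
})

test_that("posterior means match a numerical-integration oracle to 1e-8", {
  S1 <- matrix(c(1, 0.5, 0.5, 1), 2)
  S2 <- matrix(c(0.25, 0, 0, 2), 2)
  pi_c <- c(0.6, 0.4)
  Bhat <- rbind(c(0.5, -1), c(2, 1.5), c(0, 0.3))
  Shat <- rbind(c(1, 0.8), c(0.5, 1.2), c(0.9, 0.6))
  prior <- make_prior(list(a = S1, b = S2), pi = c(0, pi_c))
  post <- compute_posteriors(Bhat, Shat, prior)
  for (g in 1:3) {
    oracle <- posterior_mean_oracle_2d(Bhat[g, ], Shat[g, ]^2,
                                       list(S1, S2), pi_c)
    expect_equal(unname(post$mean[g, ]), oracle, tolerance = 1e-8)
  }
})

test_that("shrinkage contracts norms and is monotone in noise", {
  set.seed(14)
  J <- 400; R <- 3
  Bhat <- matrix(rnorm(J * R), J, R)
  Bhat[1:200, ] <- Bhat[1:200, ] * 3
  # isotropic components: posterior-mean norm never exceeds raw norm
  prior <- make_prior(list(iso = diag(R)), pi = c(0.3, 0.7),
                      scales = c(0, 1.5))
  Shat <- matrix(runif(J * R, 0.3, 2), J, R)
  post <- compute_posteriors(Bhat, Shat, prior)
  expect_true(all(rowSums(post$mean^2) <= rowSums(Bhat^2) + 1e-12))
  # same Bhat, larger Shat: smaller posterior-mean norm
  B <- Bhat[1:100, ]
  lo <- compute_posteriors(B, matrix(0.2, 100, R), prior)
  hi <- compute_posteriors(B, matrix(1.0, 100, R), prior)
  expect_true(all(rowSums(hi$mean^2) < rowSums(lo$mean^2) + 1e-12))
})

test_that("posterior draws are reproducible and match analytic moments", {
  prior <- make_prior(list(iso = diag(2)), pi = c(0.2, 0.8))
  Bhat <- matrix(c(1.5, -0.5), 1, 2); Shat <- matrix(1, 1, 2)
  post <- compute_posteriors(Bhat, Shat, prior)
  d1 <- draw_posterior_samples(post, n_draws = 100, seed = 99)
  d2 <- draw_posterior_samples(post, n_draws = 100, seed = 99)
  expect_identical(d1, d2)
  big <- draw_posterior_samples(post, n_draws = 1e5, seed = 100)
  mc_mean <- apply(big[1, , ], 2, mean)
  mc_se <- apply(big[1, , ], 2, sd) / sqrt(1e5)
  expect_true(all(abs(mc_mean - post$mean[1, ]) < 3 * mc_se))
  # pure-null prior: all draws exactly zero
  pnull <- make_prior(list(iso = diag(2)), pi = c(1, 0))
  postn <- compute_posteriors(Bhat, Shat, pnull)
  dn <- draw_posterior_samples(postn, n_draws = 10, seed = 1)
  expect_true(all(dn == 0))
  expect_error(draw_posterior_samples(post, n_draws = 0), ">= 1")
})
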