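# Shared fixtures built in code.

# Independent weighted-least-squares oracle: (X'WX)^-1 X'Wy via pseudo-inverse.
wls_oracle <- function(X, y, w = rep(1, length(y))) {
  Xw <- X * sqrt(w)
  yw <- y * sqrt(w)
  as.numeric(solve(crossprod(Xw), crossprod(Xw, yw)))
}

# A minimal single-component shrinkage prior with unit scale.
make_prior <- function(U_list, pi, scales = c(0, 1)) {
  structure(list(U = U_list, scales = scales, pi = pi,
                 labels = c("null", names(U_list)),
                 loglik_trace = numeric(0), converged = TRUE),
            class = "rhythm_prior")
}

# Dense-grid numerical-integration oracle for the mixture posterior mean in
# R = 2: prior sum_c pi_c N(0, Sigma_c), likelihood N(bhat; b, diag(s2)).
posterior_mean_oracle_2d <- function(bhat, s2, Sigmas, pi_c, L = 10, h = 0.02) {
  g <- seq(-L, L, by = h)
  b1 <- rep(g, times = length(g))
  b2 <- rep(g, each = length(g))
  dens <- 0
  for (c in seq_along(Sigmas)) {
    S <- Sigmas[[c]]
    det_s <- S[1, 1] * S[2, 2] - S[1, 2]^2
    inv <- matrix(c(S[2, 2], -S[1, 2], -S[1, 2], S[1, 1]), 2) / det_s
    q <- inv[1, 1] * b1^2 + 2 * inv[1, 2] * b1 * b2 + inv[2, 2] * b2^2
    dens <- dens + pi_c[c] * exp(-q / 2) / (2 * pi * sqrt(det_s))
  }
  lik <- exp(-((bhat[1] - b1)^2 / s2[1] + (bhat[2] - b2)^2 / s2[2]) / 2)
  post <- dens * lik
  Z <- sum(post)
  c(sum(b1 * post), sum(b2 * post)) / Z
}
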