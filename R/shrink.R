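#' Select strong signals for data-driven prior covariances
#'
#' Ranks features by their maximum absolute z-statistic `|Bhat/Shat|` across
#' coefficients and returns the indices of the top features exceeding `z_min`,
#' capped at `max_features`. Ties are broken by input order. If no feature
#' exceeds `z_min`, falls back to the top `max_features` by rank with a
#' warning.
#'
#' @param Bhat Feature-by-coefficient matrix of raw estimates.
#' @param Shat Matching matrix of standard errors (> 0).
#' @param z_min Minimum max-|z| to count as strong (default 4).
#' @param max_features Cap on the number selected (default 2000).
#' @return Integer vector of row indices, ranked by decreasing max |z|.
#' @export
select_strong_signals <- function(Bhat, Shat, z_min = 4, max_features = 2000) {
  Bhat <- as.matrix(Bhat); Shat <- as.matrix(Shat)
  if (nrow(Bhat) == 0L) stop("empty coefficient panel")
  if (any(Shat <= 0)) stop("all standard errors must be > 0")
  zmax <- apply(abs(Bhat / Shat), 1, max)
  ord <- order(-zmax, seq_along(zmax))  # stable: ties by input order
  n_strong <- sum(zmax >= z_min)
  if (n_strong == 0L) {
    warning("no features with max |z| >= ", z_min,
            "; falling back to top ", max_features, " by rank")
    return(ord[seq_len(min(max_features, length(ord)))])
  }
  ord[seq_len(min(max_features, n_strong))]
}

#' Data-driven prior covariance components from strong signals
#'
#' From the SVD of the strong-signal coefficient matrix, emits one rank-1
#' component `v_p v_p'` per top principal axis `p = 1..n_pcs`, plus the
#' rank-`n_pcs` reconstruction covariance, all scaled to unit spectral norm.
#' The number of principal components conventionally equals the number of
#' spline knots.
#'
#' @param strong_Z Matrix of coefficient estimates for the selected strong
#'   features (rows) by coefficient (columns).
#' @param n_pcs Number of principal axes (default `ncol(strong_Z)` capped at
#'   row count - 1).
#' @return Named list of symmetric PSD matrices with spectral norm 1.
#' @export
data_driven_covariances <- function(strong_Z, n_pcs = NULL) {
  strong_Z <- as.matrix(strong_Z)
  R <- ncol(strong_Z)
  if (is.null(n_pcs)) n_pcs <- min(R, nrow(strong_Z) - 1L)
  if (nrow(strong_Z) <= n_pcs)
    stop("need more than ", n_pcs, " strong features for ", n_pcs, " PCs")
  if (all(strong_Z == 0)) stop("degenerate strong-signal matrix (all zero)")
  sv <- svd(strong_Z, nu = 0, nv = n_pcs)
  d <- sv$d[seq_len(n_pcs)]
  if (d[1] <= 0) stop("degenerate strong-signal matrix (zero variance)")
  U <- list()
  for (p in seq_len(n_pcs)) {
    if (d[p] <= 0) next
    v <- sv$v[, p]
    U[[paste0("pca_", p)]] <- tcrossprod(v)      # unit spectral norm by construction
  }
  recon <- sv$v %*% (d^2 * t(sv$v))
  U[["pca_recon"]] <- recon / d[1]^2             # spectral norm 1
  lapply(U, function(u) (u + t(u)) / 2)
}

#' Scale grid for the shrinkage prior
#'
#' Geometric grid of standard-deviation scales with ratio sqrt(2) spanning
#' `[min(Shat)/10, 2 * max(|Bhat|)]`, with an exact 0 prepended as the null
#' scale. Scales are applied squared to the covariance components. The number
#' of positive scales is capped at 40 (keeping the largest) to bound the
#' mixture size when standard errors are tiny.
#'
#' @param Bhat,Shat Coefficient estimates and standard errors.
#' @return Numeric vector of scales starting with 0, then strictly increasing.
#' @export
build_scale_grid <- function(Bhat, Shat) {
  if (length(Bhat) == 0L) stop("empty coefficient panel")
  if (any(Shat <= 0)) stop("all standard errors must be > 0")
  smin <- min(Shat) / 10
  smax <- 2 * max(abs(Bhat))
  if (smax <= 0) return(c(0, smin))
  n_step <- max(0L, ceiling(log(smax / smin) / log(sqrt(2))))
  grid <- smin * sqrt(2)^(0:n_step)
  if (length(grid) > 40L) grid <- grid[(length(grid) - 39L):length(grid)]
  c(0, grid)
}

# internal: expand covariance components x scales into an R x R x C cube
# component 1 is the exact null (zero matrix); labels track (component, scale)
build_prior_cube <- function(U_list, scales, R) {
  pos <- scales[scales > 0]
  C <- 1L + length(U_list) * length(pos)
  cube <- array(0, dim = c(R, R, C))
  labels <- character(C)
  labels[1] <- "null"
  i <- 1L
  for (w in pos) {
    for (u in seq_along(U_list)) {
      i <- i + 1L
      cube[, , i] <- w^2 * U_list[[u]]
      labels[i] <- sprintf("%s;scale=%.4g", names(U_list)[u], w)
    }
  }
  list(cube = cube, labels = labels)
}

# internal: EM for mixture weights given a fixed J x C log-likelihood matrix
em_mixture_weights <- function(loglik, max_iter = 500, tol = 1e-6) {
  J <- nrow(loglik); C <- ncol(loglik)
  if (any(!is.finite(loglik) & loglik != -Inf))
    stop("non-finite log-likelihood at feature ",
         which(!is.finite(rowSums(loglik)))[1])
  mx <- apply(loglik, 1, max)
  L <- exp(loglik - mx)                      # J x C, scaled likelihoods
  pi_hat <- rep(1 / C, C)
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    num <- L %*% pi_hat                      # J x 1
    obj <- sum(log(num) + mx)
    trace <- c(trace, obj)
    resp_sum <- crossprod(L / as.numeric(num), rep(1, J))  # colSums of resp
    pi_new <- as.numeric(resp_sum * pi_hat) / J
    pi_new <- pi_new / sum(pi_new)
    if (it > 1 && abs(trace[it] - trace[it - 1]) <
        tol * (abs(trace[it - 1]) + 1e-8)) {
      pi_hat <- pi_new
      break
    }
    pi_hat <- pi_new
  }
  list(pi = pi_hat, loglik_trace = trace, n_iter = length(trace),
       converged = length(trace) < max_iter)
}

#' Fit mixture weights of the shrinkage prior by EM
#'
#' Given covariance components and a scale grid, models each feature's raw
#' coefficient vector as `Bhat_g ~ N(0, w^2 U + diag(Shat_g^2))` under a
#' mixture over components and scales (plus an exact null), and maximises the
#' marginal likelihood over the mixture weights by EM. The log-likelihood is
#' non-decreasing across iterations.
#'
#' @param Bhat,Shat Feature-by-coefficient estimate and standard-error
#'   matrices.
#' @param U_list Named list of symmetric PSD covariance components.
#' @param scales Numeric scale grid including 0 (see [build_scale_grid()]).
#' @param max_iter,tol EM iteration cap and relative log-likelihood tolerance.
#' @return Object of class `"rhythm_prior"`: list with `U`, `scales`, `pi`,
#'   `labels`, `loglik_trace`, `converged`.
#' @export
fit_mixture_weights <- function(Bhat, Shat, U_list, scales,
                                max_iter = 500, tol = 1e-6) {
  Bhat <- as.matrix(Bhat); Shat <- as.matrix(Shat)
  stopifnot(all(dim(Bhat) == dim(Shat)))
  if (any(Shat <= 0)) stop("all standard errors must be > 0")
  pc <- build_prior_cube(U_list, scales, ncol(Bhat))
  ll <- mix_loglik(Bhat, Shat, pc$cube)
  if (any(!is.finite(ll) & ll != -Inf)) {
    bad <- which(!is.finite(ll) & ll != -Inf, arr.ind = TRUE)[1, ]
    stop("non-finite likelihood for feature ", bad[1], ", component ",
         pc$labels[bad[2]])
  }
  em <- em_mixture_weights(ll, max_iter = max_iter, tol = tol)
  structure(list(U = U_list, scales = scales, pi = em$pi, labels = pc$labels,
                 loglik_trace = em$loglik_trace, converged = em$converged),
            class = "rhythm_prior")
}

#' Posterior moments under a fitted shrinkage prior
#'
#' For each feature computes mixture responsibilities, per-component Gaussian
#' posterior moments, the overall posterior mean, and the posterior SD by the
#' law of total variance.
#'
#' @param Bhat,Shat Estimate and standard-error matrices.
#' @param prior A `"rhythm_prior"` from [fit_mixture_weights()].
#' @return Object of class `"rhythm_posterior"`: list with `mean`, `sd`
#'   (feature x coefficient), `responsibilities` (feature x component),
#'   `prior`, and the `Bhat`/`Shat` the posterior refers to.
#' @export
compute_posteriors <- function(Bhat, Shat, prior) {
  stopifnot(inherits(prior, "rhythm_prior"))
  Bhat <- as.matrix(Bhat); Shat <- as.matrix(Shat)
  if (any(Shat <= 0)) stop("all standard errors must be > 0")
  pc <- build_prior_cube(prior$U, prior$scales, ncol(Bhat))
  post <- mix_posterior(Bhat, Shat, pc$cube, prior$pi)
  dimnames(post$mean) <- dimnames(Bhat)
  dimnames(post$sd) <- dimnames(Bhat)
  structure(list(mean = post$mean, sd = post$sd,
                 responsibilities = post$responsibilities,
                 prior = prior, Bhat = Bhat, Shat = Shat),
            class = "rhythm_posterior")
}

#' Draw samples from the mixture posterior
#'
#' Per feature and draw, samples a mixture component according to the
#' feature's responsibilities, then a multivariate normal from that
#' component's posterior. Reproducible under `set.seed()`.
#'
#' @param posterior A `"rhythm_posterior"` from [compute_posteriors()].
#' @param n_draws Number of posterior samples (default 200).
#' @param seed Optional integer seed set before drawing.
#' @return Array `features x draws x coefficients`.
#' @export
draw_posterior_samples <- function(posterior, n_draws = 200, seed = NULL) {
  stopifnot(inherits(posterior, "rhythm_posterior"))
  if (!(is.numeric(n_draws) && length(n_draws) == 1L && n_draws >= 1))
    stop("'n_draws' must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  pc <- build_prior_cube(posterior$prior$U, posterior$prior$scales,
                         ncol(posterior$Bhat))
  draws <- mix_draws(posterior$Bhat, posterior$Shat, pc$cube,
                     posterior$prior$pi, as.integer(n_draws))
  aperm(draws, c(1, 3, 2))
}

#' One-call adaptive shrinkage of a coefficient panel
#'
#' Convenience wrapper running strong-signal selection, data-driven covariance
#' construction, scale-grid building, EM weight fitting and posterior
#' computation.
#'
#' @param Bhat,Shat Estimate and standard-error matrices.
#' @param n_pcs Principal components for the data-driven covariances
#'   (conventionally the number of spline knots).
#' @param z_min,max_strong Strong-signal selection parameters.
#' @param max_iter,tol EM controls.
#' @return A `"rhythm_posterior"` (with the fitted prior in `$prior`).
#' @export
shrink_coefficients <- function(Bhat, Shat, n_pcs,
                                z_min = 4, max_strong = 2000,
                                max_iter = 500, tol = 1e-6) {
  strong <- select_strong_signals(Bhat, Shat, z_min = z_min,
                                  max_features = max_strong)
  if (length(strong) <= n_pcs) {
    warning("too few strong signals for ", n_pcs,
            " PCs; extending selection by rank")
    zmax <- apply(abs(as.matrix(Bhat) / as.matrix(Shat)), 1, max)
    strong <- order(-zmax, seq_along(zmax))[seq_len(min(nrow(Bhat), n_pcs + 2L))]
  }
  U <- data_driven_covariances(as.matrix(Bhat)[strong, , drop = FALSE], n_pcs)
  scales <- build_scale_grid(Bhat, Shat)
  prior <- fit_mixture_weights(Bhat, Shat, U, scales,
                               max_iter = max_iter, tol = tol)
  compute_posteriors(Bhat, Shat, prior)
}

#' @export
print.rhythm_prior <- function(x, ...) {
  cat("rhythm shrinkage prior: ", length(x$labels), " mixture components (",
      length(x$U), " covariances x ", sum(x$scales > 0),
      " scales + null)\n", sep = "")
  cat("  null weight: ", format(x$pi[1], digits = 4),
      "; EM ", length(x$loglik_trace), " iterations, ",
      if (x$converged) "converged" else "NOT converged", "\n", sep = "")
  invisible(x)
}

#' @export
print.rhythm_posterior <- function(x, ...) {
  cat("rhythm shrinkage posterior: ", nrow(x$mean), " features x ",
      ncol(x$mean), " coefficients\n", sep = "")
  print(x$prior)
  invisible(x)
}
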