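# internal: uniform half-open grid over [0, period)
time_grid <- function(period, grid_size) {
  seq(0, period, length.out = grid_size + 1L)[seq_len(grid_size)]
}

# internal: averaged time-basis matrix on a set of times, columns matching the
# assembled coefficient panel (shift-major), each divided by the number of
# shifts so that curve = mean intercept + basis %*% coef
panel_basis <- function(times, period, kind, n_knots, shifts) {
  m <- length(shifts)
  do.call(cbind, lapply(shifts, function(d)
    time_basis(times, period, kind, n_knots, d) / m))
}

# internal: per-feature constant offset of covariates at their reference level
# (first level of categoricals, mean of numeric covariates)
covariate_offset <- function(raw, covariates) {
  if (is.null(raw$cov_coef) || is.null(covariates))
    return(rep(0, length(raw$feature_ids)))
  ref <- lapply(covariates, function(v) {
    if (is.numeric(v)) mean(v)
    else factor(levels(factor(v))[1], levels = levels(factor(v)))
  })
  ref_row <- stats::model.matrix(~ ., data = as.data.frame(ref))[, -1, drop = FALSE]
  as.numeric(raw$cov_coef %*% t(ref_row))
}

#' Evaluate fitted curves on a uniform grid
#'
#' Evaluates each feature's fitted curve, averaged over the knot-shifted
#' models, on a uniform `grid_size`-point grid over `[0, tau)`. Covariates,
#' if present, contribute at their reference level (first factor level, mean
#' of numeric covariates).
#'
#' @param object A `"rhythmfit"` from [rhythmfit()].
#' @param type `"posterior"` (moderated coefficients; default when shrinkage
#'   was run) or `"raw"`.
#' @param grid_size Number of grid points G (default 512, >= 64).
#' @return Feature-by-grid matrix with the grid times (hours) in attribute
#'   `"time"`.
#' @export
evaluate_curves <- function(object, type = c("posterior", "raw"),
                            grid_size = 512) {
  stopifnot(inherits(object, "rhythmfit"))
  type <- match.arg(type)
  if (grid_size < 64) stop("'grid_size' must be >= 64")
  if (type == "posterior" && is.null(object$posterior))
    stop("fit has no posterior (run rhythmfit with shrink = TRUE)")
  raw <- object$raw
  coef_panel <- if (type == "posterior") object$posterior$mean else raw$Bhat
  grid <- time_grid(object$period, grid_size)
  Xg <- panel_basis(grid, object$period, object$basis, object$n_knots,
                    raw$shifts)
  base_level <- rowMeans(raw$intercepts) +
    covariate_offset(raw, object$experiment$covariates)
  V <- coef_panel %*% t(Xg) + base_level
  rownames(V) <- raw$feature_ids
  attr(V, "time") <- grid
  V
}

#' Rhythm statistics of fitted curves
#'
#' Computes the seven rhythm statistics of a periodic curve sampled on a
#' uniform grid over one period: mesor (grid mean), peak and trough values,
#' their phases (first-occurrence grid argmax/argmin, hours), peak-to-trough
#' amplitude, and RMS amplitude (the square root of the mean squared
#' deviation from the mesor, the Riemann approximation of the amplitude
#' integral). A constant curve gets phases 0 by the tie rule and is flagged
#' `degenerate`.
#'
#' @param curve Numeric vector (one curve) or matrix (curves in rows) of
#'   values on a uniform grid over `[0, period)`.
#' @param period Period tau in hours.
#' @return data.frame with columns `mesor`, `peak`, `peak_phase`, `trough`,
#'   `trough_phase`, `ptr_amp`, `rms_amp`, `degenerate`; one row per curve.
#' @examples
#' g <- seq(0, 24, length.out = 513)[1:512]
#' compute_rhythm_stats(5 + 2 * cos(2 * pi * g / 24), period = 24)
#' @export
compute_rhythm_stats <- function(curve, period = 24) {
  V <- if (is.matrix(curve)) curve else matrix(curve, nrow = 1)
  if (any(!is.finite(V))) stop("curve values must be finite")
  G <- ncol(V)
  grid <- time_grid(period, G)
  mesor <- rowMeans(V)
  imax <- max.col(V, ties.method = "first")
  imin <- max.col(-V, ties.method = "first")
  idx <- seq_len(nrow(V))
  peak <- V[cbind(idx, imax)]
  trough <- V[cbind(idx, imin)]
  ptr <- peak - trough
  out <- data.frame(
    mesor = mesor, peak = peak, peak_phase = grid[imax],
    trough = trough, trough_phase = grid[imin],
    ptr_amp = ptr,
    rms_amp = sqrt(rowMeans((V - mesor)^2)),
    degenerate = ptr == 0)
  if (!is.null(rownames(V)) && !anyDuplicated(rownames(V)))
    rownames(out) <- rownames(V)
  out
}

#' Signed amplitudes via the circular-mean-phase sign-flip rule
#'
#' Amplitude estimates are non-negative, so amplitude credible intervals
#' would never span zero even for arrhythmic features. This rule negates the
#' amplitude of posterior draws whose peak phase lies more than a quarter
#' period (in circular distance) from the amplitude-weighted circular mean
#' peak phase, letting intervals of highly uncertain rhythms span zero.
#'
#' @param amplitude Per-draw amplitudes to sign (e.g. peak-to-trough or RMS).
#' @param peak_phase Per-draw peak phases in hours.
#' @param period Period tau.
#' @param weights Weights for the circular mean phase; by convention the
#'   peak-to-trough amplitudes (default `amplitude`).
#' @return Numeric vector of signed amplitudes with attributes
#'   `reference_phase` (hours; `NA` if all weights are zero), `flipped`
#'   (logical per draw) and `degenerate`.
#' @export
signed_amplitude <- function(amplitude, peak_phase, period = 24,
                             weights = amplitude) {
  stopifnot(length(amplitude) == length(peak_phase),
            length(weights) == length(peak_phase))
  theta <- 2 * pi * peak_phase / period
  sw <- sum(weights * sin(theta))
  cw <- sum(weights * cos(theta))
  if (all(weights == 0) || (sw == 0 && cw == 0)) {
    out <- amplitude
    attr(out, "reference_phase") <- NA_real_
    attr(out, "flipped") <- rep(FALSE, length(amplitude))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  phi <- (atan2(sw, cw) * period / (2 * pi)) %% period
  d <- abs(peak_phase %% period - phi)
  d <- pmin(d, period - d)
  flip <- d > period / 4
  out <- ifelse(flip, -amplitude, amplitude)
  attr(out, "reference_phase") <- phi
  attr(out, "flipped") <- flip
  attr(out, "degenerate") <- FALSE
  out
}

#' Credible interval from posterior samples
#'
#' Equal-tailed: empirical quantiles at `(1 - mass)/2` and `1 - (1 - mass)/2`
#' (type-7, linear interpolation). HDI: the narrowest contiguous window of
#' `ceiling(mass * n)` sorted samples.
#'
#' @param samples Numeric vector of posterior samples (length >= 2).
#' @param mass Interval mass in (0, 1); default 0.90.
#' @param method `"equal_tailed"` (default) or `"hdi"`.
#' @return List of class `"credible_interval"` with `lower`, `upper`, `mass`,
#'   `method`.
#' @export
credible_interval <- function(samples, mass = 0.90,
                              method = c("equal_tailed", "hdi")) {
  method <- match.arg(method)
  if (!(is.numeric(mass) && length(mass) == 1L && mass > 0 && mass < 1))
    stop("'mass' must be in (0, 1)")
  samples <- samples[!is.na(samples)]
  n <- length(samples)
  if (n < 2L) stop("need at least 2 samples")
  if (method == "equal_tailed") {
    q <- stats::quantile(samples, c((1 - mass) / 2, 1 - (1 - mass) / 2),
                         names = FALSE, type = 7)
    lower <- q[1]; upper <- q[2]
  } else {
    s <- sort(samples)
    k <- min(n, ceiling(mass * n))
    i <- seq_len(n - k + 1L)
    width <- s[i + k - 1L] - s[i]
    j <- which.min(width)
    lower <- s[j]; upper <- s[j + k - 1L]
  }
  structure(list(lower = lower, upper = upper, mass = mass, method = method),
            class = "credible_interval")
}

#' @export
print.credible_interval <- function(x, ...) {
  cat(sprintf("%.0f%% %s credible interval: [%g, %g]\n", 100 * x$mass,
              x$method, x$lower, x$upper))
  invisible(x)
}

#' Rhythm statistics table of a fitted model
#'
#' Evaluates the (posterior or raw) fitted curve of every feature on a
#' uniform grid and tabulates the seven rhythm statistics.
#'
#' @inheritParams evaluate_curves
#' @return data.frame with `feature_id` and the statistics of
#'   [compute_rhythm_stats()].
#' @export
rhythm_stats <- function(object, type = c("posterior", "raw"),
                         grid_size = 512) {
  type <- match.arg(type)
  if (type == "posterior" && is.null(object$posterior)) type <- "raw"
  V <- evaluate_curves(object, type = type, grid_size = grid_size)
  st <- compute_rhythm_stats(V, period = object$period)
  cbind(feature_id = object$raw$feature_ids, st, row.names = NULL)
}

#' Credible intervals for rhythm statistics from posterior draws
#'
#' Draws coefficient samples from the shrinkage posterior, evaluates each
#' draw's curve, computes per-draw rhythm statistics, applies the
#' signed-amplitude rule to both amplitudes (weighted by the peak-to-trough
#' amplitudes), and returns per-feature credible intervals for the signed
#' amplitudes and the mesor.
#'
#' @param object A `"rhythmfit"` with a posterior.
#' @param n_draws Number of posterior samples (default 200).
#' @param mass Interval mass (default 0.90).
#' @param method `"equal_tailed"` or `"hdi"`.
#' @param seed Optional seed for the draws.
#' @param grid_size Curve grid size (default 512).
#' @return data.frame with one row per feature: `feature_id`, lower/upper
#'   bounds for `ptr_amp`, `rms_amp` and `mesor`, the draw-mean signed
#'   amplitudes, and the amplitude-weighted circular mean peak phase.
#'   Attributes `mass`, `method`, `n_draws` record the settings.
#' @export
rhythm_intervals <- function(object, n_draws = 200, mass = 0.90,
                             method = c("equal_tailed", "hdi"), seed = NULL,
                             grid_size = 512) {
  stopifnot(inherits(object, "rhythmfit"))
  method <- match.arg(method)
  if (n_draws < 2) stop("'n_draws' must be >= 2")
  if (is.null(object$posterior))
    stop("fit has no posterior (run rhythmfit with shrink = TRUE)")
  raw <- object$raw
  draws <- draw_posterior_samples(object$posterior, n_draws = n_draws,
                                  seed = seed)
  grid <- time_grid(object$period, grid_size)
  Xg <- panel_basis(grid, object$period, object$basis, object$n_knots,
                    raw$shifts)
  base_level <- rowMeans(raw$intercepts) +
    covariate_offset(raw, object$experiment$covariates)
  J <- dim(draws)[1]
  res <- vector("list", J)
  for (j in seq_len(J)) {
    curves <- draws[j, , ] %*% t(Xg) + base_level[j]
    st <- compute_rhythm_stats(curves, period = object$period)
    ptr_s <- signed_amplitude(st$ptr_amp, st$peak_phase, object$period)
    rms_s <- signed_amplitude(st$rms_amp, st$peak_phase, object$period,
                              weights = st$ptr_amp)
    ci_p <- credible_interval(ptr_s, mass, method)
    ci_r <- credible_interval(rms_s, mass, method)
    ci_m <- credible_interval(st$mesor, mass, method)
    res[[j]] <- c(ptr_amp_lower = ci_p$lower, ptr_amp_upper = ci_p$upper,
                  rms_amp_lower = ci_r$lower, rms_amp_upper = ci_r$upper,
                  mesor_lower = ci_m$lower, mesor_upper = ci_m$upper,
                  ptr_amp_mean = mean(ptr_s), rms_amp_mean = mean(rms_s),
                  peak_phase_ref = attr(ptr_s, "reference_phase"))
  }
  out <- cbind(data.frame(feature_id = raw$feature_ids),
               as.data.frame(do.call(rbind, res)))
  attr(out, "mass") <- mass
  attr(out, "method") <- method
  attr(out, "n_draws") <- n_draws
  out
}
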