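#' Moderate residual variances with an intensity trend
#'
#' Empirical-Bayes squeeze of per-feature residual variances toward a smooth
#' trend in mean expression. Log variances are smoothed against mean
#' expression (lowess) to give a trend `s2_trend`; treating the scaled
#' variances as draws from a scaled inverse-chi-square hierarchy with prior
#' df `d0`, the excess spread of the log variances beyond the sampling
#' component `trigamma(df/2)` identifies `d0` by method of moments
#' (trigamma inversion), and the posterior variance is the standard squeeze
#' `(d0 * s2_trend + df * s2) / (d0 + df)`. The trend is taken as the plain
#' exponentiated smooth (no log-scale bias correction), a simplification
#' that makes the no-spread case an exact fixed point. With fewer than 10
#' features there is too little information to estimate the hierarchy, so
#' variances are returned unmoderated with a warning.
#'
#' @param s2 Per-feature residual variances (> 0).
#' @param df Residual degrees of freedom (scalar or per feature, >= 1).
#' @param mean_expression Per-feature mean expression driving the trend.
#' @param force_d0_inf If `TRUE`, take the infinite-prior-df limit: moderated
#'   variances equal the trend values.
#' @param span Lowess span for the trend (default 0.5).
#' @return List with `var_post`, `df_prior`, `var_trend`, `df_total`.
#' @export
moderate_variances <- function(s2, df, mean_expression, force_d0_inf = FALSE,
                               span = 0.5) {
  if (any(df < 1)) stop("residual df must be >= 1")
  if (any(s2 <= 0)) stop("residual variances must be > 0")
  n <- length(s2)
  df <- rep_len(df, n)
  if (n < 10L) {
    warning("fewer than 10 features: skipping variance moderation")
    return(list(var_post = s2, df_prior = 0, var_trend = s2,
                df_total = df))
  }
  z <- log(s2)
  lo <- stats::lowess(mean_expression, z, f = span)
  trend <- stats::approx(lo$x, lo$y, xout = mean_expression, rule = 2,
                         ties = mean)$y
  var_trend <- exp(trend)
  excess <- stats::var(z - trend) - mean(trigamma(df / 2))
  d0 <- if (force_d0_inf || excess <= 0) Inf
        else 2 * limma::trigammaInverse(excess)
  if (is.infinite(d0)) {
    list(var_post = var_trend, df_prior = Inf, var_trend = var_trend,
         df_total = rep(Inf, n))
  } else {
    list(var_post = (d0 * var_trend + df * s2) / (d0 + df),
         df_prior = d0, var_trend = var_trend, df_total = df + d0)
  }
}

#' Precision weights from the count mean-variance trend
#'
#' Estimates per-observation precision weights for log-CPM of RNA-seq counts
#' by modelling the square-root residual standard deviation as a smooth
#' function of average log-count and taking predicted variance to the power
#' -1 at each observation's fitted value (the voom approach; delegates to
#' `limma::voom`).
#'
#' @param counts Nonnegative integer-like feature-by-sample count matrix.
#' @param design Model design matrix (samples x coefficients).
#' @param span Smoother span (default 0.5).
#' @return List with `weights` (feature x sample, positive finite) and `E`
#'   (the log2-CPM values voom models).
#' @export
estimate_precision_weights <- function(counts, design, span = 0.5) {
  counts <- as.matrix(counts)
  if (any(counts < 0, na.rm = TRUE) ||
      any(abs(counts - round(counts)) > 1e-6, na.rm = TRUE))
    stop("'counts' must be nonnegative integer-like raw counts")
  v <- limma::voom(counts, design = design, span = span)
  if (any(!is.finite(v$weights)) || any(v$weights <= 0))
    stop("voom produced non-positive or non-finite weights")
  list(weights = v$weights, E = v$E)
}

# internal: build the full design matrix for one shifted model
shift_design <- function(time, period, kind, n_knots, shift, covariates) {
  B <- time_basis(time, period, kind, n_knots, shift)
  X <- cbind(`(Intercept)` = 1, B)
  if (!is.null(covariates)) {
    cd <- stats::model.matrix(~ ., data = covariates)[, -1, drop = FALSE]
    X <- cbind(X, cd)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_cols <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(drop_cols, collapse = ", "))
  }
  X
}

#' Fit the series of shifted per-feature linear models
#'
#' For each of `m` knot shifts, fits every feature's measurements on an
#' intercept, the (shifted) time basis, and any covariates by weighted least
#' squares, and extracts coefficients and standard errors. Backends:
#' `"plain"` uses each feature's own residual variance; `"trend"`
#' additionally squeezes residual variances toward the mean-expression trend
#' before computing standard errors; `"voom"` expects per-observation
#' precision weights estimated from counts (see
#' [estimate_precision_weights()]), shared across shifts.
#'
#' @param experiment A [rhythm_experiment()] with log-scale measurements.
#' @param n_knots Spline knots (default 3; ignored for cosinor).
#' @param n_shifts Number of shifted models m (default 3; forced to 1 for
#'   cosinor, whose basis is shift-invariant).
#' @param basis `"spline"` or `"cosinor"`.
#' @param backend `"plain"`, `"trend"` or `"voom"`.
#' @param weights Optional feature-by-sample weight matrix (required for
#'   `"voom"`).
#' @return Object of class `"rhythm_rawfit"`: per-shift coefficient and SE
#'   matrices, assembled time-coefficient panel (`Bhat`, `Shat`,
#'   feature x (m * basis dim)), intercepts, covariate coefficients, residual
#'   variances and df, shifts, and the design metadata.
#' @export
fit_linear_models <- function(experiment, n_knots = 3, n_shifts = 3,
                              basis = c("spline", "cosinor"),
                              backend = c("plain", "trend", "voom"),
                              weights = NULL) {
  stopifnot(inherits(experiment, "rhythm_experiment"))
  basis <- match.arg(basis)
  backend <- match.arg(backend)
  if (experiment$is_counts)
    stop("experiment holds raw counts; transform first (see rhythmfit)")
  if (basis == "cosinor") n_shifts <- 1L
  if (n_shifts < 1) stop("'n_shifts' must be >= 1")
  if (backend == "voom" && is.null(weights))
    stop("backend 'voom' requires precision weights")
  if (backend == "trend" && nrow(experiment$measurements) < 10L) {
    message("fewer than 10 features: variance moderation skipped, ",
            "using backend 'plain'")
    backend <- "plain"
  }
  y <- experiment$measurements
  time <- experiment$time
  period <- experiment$period
  shifts <- if (basis == "cosinor") 0 else knot_shifts(n_shifts, n_knots, period)
  n_time_coef <- if (basis == "cosinor") 2L else n_knots
  p_check <- 1L + n_time_coef +
    if (is.null(experiment$covariates)) 0L else
      ncol(stats::model.matrix(~ ., data = experiment$covariates)) - 1L
  n_used <- min(rowSums(!is.na(y)))
  if (n_used < p_check + 1L)
    stop("fewer usable samples (", n_used, ") than coefficients + 1 (",
         p_check + 1L, ")")

  fits <- vector("list", n_shifts)
  for (k in seq_len(n_shifts)) {
    X <- shift_design(time, period, basis, n_knots, shifts[k],
                      experiment$covariates)
    lf <- limma::lmFit(y, design = X, weights = weights)
    if (backend == "trend") {
      eb <- limma::eBayes(lf, trend = TRUE)
      s2 <- eb$s2.post
      df_total <- lf$df.residual + eb$df.prior
    } else if (backend == "voom") {
      eb <- limma::eBayes(lf)
      s2 <- eb$s2.post
      df_total <- lf$df.residual + eb$df.prior
    } else {
      s2 <- lf$sigma^2
      df_total <- lf$df.residual
    }
    se <- lf$stdev.unscaled * sqrt(s2)
    fits[[k]] <- list(coef = lf$coefficients, se = se, s2 = s2,
                      df_residual = lf$df.residual, df_total = df_total,
                      shift = shifts[k], design = X)
  }

  time_cols <- 1L + seq_len(n_time_coef)
  Bhat <- do.call(cbind, lapply(seq_len(n_shifts), function(k) {
    m <- fits[[k]]$coef[, time_cols, drop = FALSE]
    colnames(m) <- paste0("k", k, "_", colnames(m))
    m
  }))
  Shat <- do.call(cbind, lapply(seq_len(n_shifts), function(k) {
    m <- fits[[k]]$se[, time_cols, drop = FALSE]
    colnames(m) <- paste0("k", k, "_", colnames(m))
    m
  }))
  intercepts <- vapply(fits, function(f) f$coef[, 1L], numeric(nrow(y)))
  if (nrow(y) == 1L) intercepts <- matrix(intercepts, nrow = 1L)
  cov_cols <- setdiff(seq_len(ncol(fits[[1]]$coef)), c(1L, time_cols))
  cov_coef <- if (length(cov_cols))
    fits[[1]]$coef[, cov_cols, drop = FALSE] else NULL

  structure(
    list(fits = fits, Bhat = Bhat, Shat = Shat,
         intercepts = intercepts, cov_coef = cov_coef,
         shifts = shifts, basis = basis, n_knots = n_knots,
         n_shifts = n_shifts, backend = backend,
         feature_ids = experiment$feature_ids,
         period = period, weights = weights),
    class = "rhythm_rawfit")
}

#' Fit rhythmicity models with empirical-Bayes shrinkage
#'
#' The main entry point: fits each feature of a genomic time series with a
#' series of knot-shifted periodic-spline (or cosinor) linear models, then
#' moderates the time coefficients across features with an adaptive-shrinkage
#' mixture prior, yielding posterior fitted curves whose rhythm statistics
#' and credible intervals can be extracted with [rhythm_stats()],
#' [rhythm_intervals()], [summary.rhythmfit()], [predict.rhythmfit()] and
#' [plot.rhythmfit()].
#'
#' If the experiment holds raw counts, they are first filtered by CPM,
#' zero-imputed, and either log2-CPM transformed (backend `"trend"`) or
#' passed to voom for precision weights (backend `"voom"`, the default for
#' counts).
#'
#' @param object A [rhythm_experiment()], or a feature-by-sample matrix (then
#'   `time` must be given).
#' @param time Sample times in hours when `object` is a matrix.
#' @param period Rhythm period tau in hours (default 24).
#' @param n_knots Number of spline knots (default 3).
#' @param n_shifts Number of knot-shifted models m (default 3).
#' @param basis `"spline"` (default) or `"cosinor"`.
#' @param backend `"auto"` (default: `"trend"` for log data, `"voom"` for
#'   counts), `"plain"`, `"trend"` or `"voom"`.
#' @param shrink Apply coefficient shrinkage (default `TRUE`). With
#'   `FALSE` only the raw fits are computed.
#' @param covariates Optional per-sample covariate data.frame (overrides any
#'   in the experiment).
#' @param cpm_threshold,min_fraction,prior_count Count preprocessing
#'   parameters (see [filter_low_expression()], [log_cpm()]).
#' @param z_min,max_strong,max_iter,tol Shrinkage controls (see
#'   [shrink_coefficients()]).
#' @param ... Unused.
#' @return Object of class `"rhythmfit"`.
#' @examples
#' sim <- simulate_rhythm_data(n_genes = 30, seed = 1)
#' fit <- rhythmfit(sim$experiment)
#' head(summary(fit)$stats)
#' @export
rhythmfit <- function(object, time = NULL, period = 24, n_knots = 3,
                      n_shifts = 3, basis = c("spline", "cosinor"),
                      backend = c("auto", "plain", "trend", "voom"),
                      shrink = TRUE, covariates = NULL,
                      cpm_threshold = 0.5, min_fraction = 0.75,
                      prior_count = 0.5, z_min = 4, max_strong = 2000,
                      max_iter = 500, tol = 1e-6, ...) {
  basis <- match.arg(basis)
  backend <- match.arg(backend)
  cl <- match.call()
  if (!inherits(object, "rhythm_experiment")) {
    if (is.null(time)) stop("'time' is required when 'object' is a matrix")
    object <- rhythm_experiment(object, time = time, period = period,
                                covariates = covariates)
  } else if (!is.null(covariates)) {
    object$covariates <- as.data.frame(covariates)
  }
  experiment <- object
  if (backend == "auto") backend <- if (experiment$is_counts) "voom" else "trend"

  weights <- NULL
  preprocess <- NULL
  if (experiment$is_counts) {
    counts <- experiment$measurements
    keep <- filter_low_expression(counts, cpm_threshold, min_fraction)
    counts <- impute_zero_counts(counts[keep, , drop = FALSE])
    preprocess <- list(n_input = nrow(experiment$measurements),
                       kept = experiment$feature_ids[keep],
                       cpm_threshold = cpm_threshold,
                       min_fraction = min_fraction)
    if (backend == "voom") {
      X1 <- shift_design(experiment$time, experiment$period, basis, n_knots,
                         0, experiment$covariates)
      pw <- estimate_precision_weights(counts, X1)
      weights <- pw$weights
      logm <- pw$E
    } else {
      logm <- log_cpm(counts, prior_count = prior_count)
    }
    experiment <- rhythm_experiment(logm, time = experiment$time,
                                    period = experiment$period,
                                    covariates = experiment$covariates,
                                    is_counts = FALSE)
  } else if (backend == "voom") {
    stop("backend 'voom' requires a count experiment (is_counts = TRUE)")
  }

  raw <- fit_linear_models(experiment, n_knots = n_knots, n_shifts = n_shifts,
                           basis = basis, backend = backend, weights = weights)
  posterior <- NULL
  if (shrink) {
    n_pcs <- if (basis == "cosinor") 2L else n_knots
    posterior <- shrink_coefficients(raw$Bhat, raw$Shat, n_pcs = n_pcs,
                                     z_min = z_min, max_strong = max_strong,
                                     max_iter = max_iter, tol = tol)
  }
  structure(
    list(experiment = experiment, raw = raw, posterior = posterior,
         basis = basis, n_knots = n_knots, n_shifts = raw$n_shifts,
         backend = backend, period = experiment$period,
         preprocess = preprocess, call = cl),
    class = "rhythmfit")
}
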