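#' Knot shifts for the series of shifted spline models
#'
#' For `m` models with a periodic spline on `n` knots and period `tau`, model
#' `k` uses shift `d_k = (k - 1) * tau / (m * (n + 1))`. The n-knot periodic
#' spline has n + 1 uniformly spaced knots on the circle (spacing
#' `tau / (n + 1)`), so the m shifts tile exactly one inter-knot spacing.
#'
#' @param m Number of shifted models (>= 1).
#' @param n_knots Number of spline knots (>= 2).
#' @param period Period tau in hours.
#' @return Numeric vector of m shifts, starting at 0, strictly increasing.
#' @examples
#' knot_shifts(3, 3, 24) # 0, 2, 4
#' @export
knot_shifts <- function(m, n_knots, period = 24) {
  if (!(is.numeric(m) && length(m) == 1L && m >= 1 && m == round(m)))
    stop("'m' must be a positive integer")
  if (!(is.numeric(n_knots) && length(n_knots) == 1L && n_knots >= 2 && n_knots == round(n_knots)))
    stop("'n_knots' must be an integer >= 2")
  if (!(is.numeric(period) && length(period) == 1L && period > 0))
    stop("'period' must be > 0")
  (seq_len(m) - 1) * period / (m * (n_knots + 1))
}

#' Periodic cubic B-spline basis
#'
#' Evaluates a periodic cubic B-spline basis with period `tau` and `n_knots`
#' internal knots, i.e. n + 1 uniformly spaced knots on the circle at
#' `(j * tau / (n + 1) + shift) mod tau`, j = 0..n. The full periodic basis
#' has n + 1 columns summing to 1 (partition of unity); by default the last
#' column is dropped so that an intercept plus the returned `n` columns spans
#' the same function space (the model carries a separate intercept). Every
#' column is tau-periodic and C2-continuous across the period boundary. Times
#' may be negative; they are reduced modulo tau.
#'
#' @param times Numeric vector of times (hours).
#' @param period Period tau (> 0).
#' @param n_knots Number of internal knots n (>= 2); default 3.
#' @param shift Knot shift d in hours (default 0).
#' @param drop_constant If `TRUE` (default) return n columns for use alongside
#'   an intercept; if `FALSE` return the full (n + 1)-column periodic basis.
#' @return Matrix with one row per time.
#' @export
periodic_spline_basis <- function(times, period = 24, n_knots = 3, shift = 0,
                                  drop_constant = TRUE) {
  n <- n_knots
  if (!(is.numeric(n) && length(n) == 1L && n >= 2 && n == round(n)))
    stop("'n_knots' must be an integer >= 2")
  if (!(is.numeric(period) && length(period) == 1L && period > 0))
    stop("'period' must be > 0")
  h <- period / (n + 1)
  circle <- (0:n) * h
  x <- (times - shift) %% period
  # extended knot vector: wrap three knots past each end for degree 3
  ext <- c(circle[(n - 1):(n + 1)] - period, circle, period, circle[2:4] + period)
  full <- splines::splineDesign(ext, x, ord = 4L, outer.ok = TRUE)
  # identify B-splines whose support wraps the period boundary
  P <- full[, 1:(n + 1), drop = FALSE]
  for (i in 1:3) P[, i] <- P[, i] + full[, i + n + 1L]
  colnames(P) <- paste0("pspl", seq_len(n + 1))
  if (drop_constant) P[, seq_len(n), drop = FALSE] else P
}

#' Cosinor basis
#'
#' Cosine and sine of the time angle `theta = 2 * pi * t / tau`; together with
#' an intercept this is the classical cosinor regression basis, capturing pure
#' sinusoids of period tau only.
#'
#' @param times Numeric vector of times (hours).
#' @param period Period tau (> 0).
#' @return Matrix with columns `cos` and `sin`, one row per time.
#' @export
cosinor_basis <- function(times, period = 24) {
  if (!(is.numeric(period) && length(period) == 1L && period > 0))
    stop("'period' must be > 0")
  theta <- 2 * pi * times / period
  cbind(cos = cos(theta), sin = sin(theta))
}

# internal: time basis for one shifted model
time_basis <- function(times, period, kind, n_knots, shift) {
  if (kind == "cosinor") cosinor_basis(times, period)
  else periodic_spline_basis(times, period, n_knots, shift)
}
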