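#' @export
print.rhythmfit <- function(x, ...) {
  cat("Rhythmicity fit (", x$basis, " basis)\n", sep = "")
  cat("  features: ", length(x$raw$feature_ids), "; samples: ",
      ncol(x$experiment$measurements), "; period: ", x$period, " h\n", sep = "")
  if (x$basis == "spline")
    cat("  knots: ", x$n_knots, "; shifted models: ", x$n_shifts,
        " (shifts ", paste(format(x$raw$shifts, digits = 3), collapse = ", "),
        " h)\n", sep = "")
  cat("  backend: ", x$backend, "\n", sep = "")
  if (!is.null(x$preprocess))
    cat("  count preprocessing: ", length(x$preprocess$kept), " of ",
        x$preprocess$n_input, " features kept (CPM >= ",
        x$preprocess$cpm_threshold, " in >= ",
        100 * x$preprocess$min_fraction, "% of samples)\n", sep = "")
  if (!is.null(x$posterior)) {
    cat("  shrinkage: ", length(x$posterior$prior$labels),
        " mixture components, null weight ",
        format(x$posterior$prior$pi[1], digits = 3), "\n", sep = "")
  } else cat("  shrinkage: none (raw fits only)\n")
  invisible(x)
}

#' Extract time coefficients
#'
#' Returns the feature-by-coefficient panel of time coefficients across all
#' shifted models; `"posterior"` gives the shrunken estimates. Per-shift
#' intercepts are attached as attribute `"intercepts"` (never moderated).
#'
#' @param object A `"rhythmfit"`.
#' @param type `"posterior"` (default when available) or `"raw"`.
#' @param ... Unused.
#' @export
coef.rhythmfit <- function(object, type = c("posterior", "raw"), ...) {
  type <- match.arg(type)
  if (type == "posterior" && is.null(object$posterior)) type <- "raw"
  out <- if (type == "posterior") object$posterior$mean else object$raw$Bhat
  attr(out, "intercepts") <- object$raw$intercepts
  out
}

#' Predict fitted curves at arbitrary times
#'
#' @param object A `"rhythmfit"`.
#' @param times Times in hours (default: the sample times).
#' @param type `"posterior"` (default when available) or `"raw"`.
#' @param features Optional feature ids or indices to evaluate.
#' @param ... Unused.
#' @return Matrix, selected features by `length(times)`.
#' @export
predict.rhythmfit <- function(object, times = NULL,
                              type = c("posterior", "raw"),
                              features = NULL, ...) {
  type <- match.arg(type)
  if (type == "posterior" && is.null(object$posterior)) type <- "raw"
  if (is.null(times)) times <- object$experiment$time
  raw <- object$raw
  coef_panel <- if (type == "posterior") object$posterior$mean else raw$Bhat
  base_level <- rowMeans(raw$intercepts) +
    covariate_offset(raw, object$experiment$covariates)
  if (!is.null(features)) {
    idx <- if (is.character(features)) match(features, raw$feature_ids)
           else features
    if (anyNA(idx)) stop("unknown feature id(s)")
    coef_panel <- coef_panel[idx, , drop = FALSE]
    base_level <- base_level[idx]
  }
  X <- panel_basis(times, object$period, object$basis, object$n_knots,
                   raw$shifts)
  out <- coef_panel %*% t(X) + base_level
  colnames(out) <- NULL
  out
}

#' @export
fitted.rhythmfit <- function(object, type = c("posterior", "raw"), ...) {
  predict(object, type = match.arg(type))
}

#' Raw-fit residuals
#'
#' Measurements minus the raw (unshrunken) average fitted curve evaluated at
#' the sample times.
#'
#' @param object A `"rhythmfit"`.
#' @param ... Unused.
#' @export
residuals.rhythmfit <- function(object, ...) {
  object$experiment$measurements - predict(object, type = "raw")
}

#' Summarise a rhythmicity fit
#'
#' @param object A `"rhythmfit"`.
#' @param type Curve type for the statistics.
#' @param grid_size Evaluation grid size.
#' @param ... Unused.
#' @return `"summary.rhythmfit"`: list with the rhythm `stats` table (sorted
#'   as fitted) and fit metadata.
#' @export
summary.rhythmfit <- function(object, type = c("posterior", "raw"),
                              grid_size = 512, ...) {
  type <- match.arg(type)
  if (type == "posterior" && is.null(object$posterior)) type <- "raw"
  structure(list(stats = rhythm_stats(object, type = type,
                                      grid_size = grid_size),
                 type = type, fit = object),
            class = "summary.rhythmfit")
}

#' @export
print.summary.rhythmfit <- function(x, n = 10, ...) {
  print(x$fit)
  st <- x$stats[order(-x$stats$ptr_amp), ]
  cat("\nTop features by ", x$type, " peak-to-trough amplitude:\n", sep = "")
  print(utils::head(st[, c("feature_id", "mesor", "ptr_amp", "rms_amp",
                           "peak_phase", "trough_phase")], n),
        row.names = FALSE, digits = 4)
  invisible(x)
}

#' Plot one feature's data and fitted curve
#'
#' Plots the measurements against time modulo the period, with the posterior
#' (and optionally raw) fitted curve overlaid.
#'
#' @param x A `"rhythmfit"`.
#' @param feature Feature id or index (default first).
#' @param show_raw Also draw the raw average fit, dashed.
#' @param grid_size Curve resolution.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.rhythmfit <- function(x, feature = 1, show_raw = FALSE,
                           grid_size = 256, ...) {
  idx <- if (is.character(feature)) match(feature, x$raw$feature_ids)
         else feature
  if (is.na(idx)) stop("unknown feature: ", feature)
  tt <- x$experiment$time %% x$period
  y <- x$experiment$measurements[idx, ]
  grid <- time_grid(x$period, grid_size)
  type <- if (is.null(x$posterior)) "raw" else "posterior"
  curve <- predict(x, times = grid, type = type, features = idx)
  graphics::plot(tt, y, xlab = "time mod period (h)", ylab = "measurement",
                 main = x$raw$feature_ids[idx], ...)
  graphics::lines(grid, curve[1, ], col = "darkgreen", lwd = 2)
  if (show_raw && !is.null(x$posterior)) {
    rawc <- predict(x, times = grid, type = "raw", features = idx)
    graphics::lines(grid, rawc[1, ], col = "orange", lty = 2, lwd = 2)
  }
  invisible(x)
}
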