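#' Filter lowly expressed features by CPM
#'
#' Retains a feature iff its counts-per-million are at least `cpm_threshold`
#' in at least `ceiling(min_fraction * n_samples)` samples, irrespective of
#' timepoint. The defaults (CPM >= 0.5 in >= 75% of samples) are the usual
#' rule for circadian RNA-seq designs.
#'
#' @param counts Nonnegative feature-by-sample count matrix.
#' @param cpm_threshold Minimum CPM (default 0.5).
#' @param min_fraction Minimum fraction of samples, in (0, 1] (default 0.75).
#' @return Integer vector of retained row indices, in input order.
#' @examples
#' counts <- rbind(a = c(1, 1, 1, 1), b = c(0, 0, 0, 100))
#' filter_low_expression(counts * 0 + counts, cpm_threshold = 0.5)
#' @export
filter_low_expression <- function(counts, cpm_threshold = 0.5, min_fraction = 0.75) {
  counts <- as.matrix(counts)
  if (nrow(counts) == 0L || ncol(counts) == 0L) stop("empty count matrix")
  if (any(counts < 0, na.rm = TRUE)) stop("counts must be nonnegative")
  if (!(cpm_threshold >= 0)) stop("'cpm_threshold' must be >= 0")
  if (!(min_fraction > 0 && min_fraction <= 1)) stop("'min_fraction' must be in (0, 1]")
  lib <- colSums(counts)
  if (any(lib <= 0)) {
    bad <- colnames(counts)[lib <= 0]
    if (is.null(bad)) bad <- which(lib <= 0)
    stop("zero library size in sample(s): ", paste(bad, collapse = ", "))
  }
  cpm <- sweep(counts, 2, lib, "/") * 1e6
  need <- ceiling(min_fraction * ncol(counts))
  which(rowSums(cpm >= cpm_threshold) >= need)
}

#' Impute zero counts with the per-feature minimum nonzero count
#'
#' Replaces every zero in a row with that row's minimum nonzero count; nonzero
#' entries are unchanged. Avoids unrealistically low log-transformed CPM
#' values (and hence inflated amplitude estimates) for genes with occasional
#' dropout.
#'
#' @param counts Feature-by-sample count matrix; every row must contain at
#'   least one nonzero count.
#' @return Matrix of the same shape.
#' @examples
#' impute_zero_counts(rbind(c(0, 3, 7, 5)))
#' @export
impute_zero_counts <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0, na.rm = TRUE)) stop("counts must be nonnegative")
  nz_min <- apply(counts, 1, function(r) {
    r <- r[!is.na(r) & r > 0]
    if (!length(r)) NA_real_ else min(r)
  })
  if (anyNA(nz_min)) {
    bad <- rownames(counts)[is.na(nz_min)]
    if (is.null(bad)) bad <- which(is.na(nz_min))
    stop("all-zero feature row(s), cannot impute: ",
         paste(head(bad, 5), collapse = ", "))
  }
  zero <- !is.na(counts) & counts == 0
  counts[zero] <- nz_min[row(counts)[zero]]
  counts
}

#' Log2-CPM transform
#'
#' Computes `log2((count + prior_count) / (library_size + 2 * prior_count) * 1e6)`
#' per entry, the standard moderated log-CPM used before linear modelling of
#' counts.
#'
#' @param counts Nonnegative feature-by-sample count matrix.
#' @param prior_count Pseudocount (default 0.5).
#' @param lib_size Optional library sizes; default column sums.
#' @return Matrix of log2-CPM values, same shape and dimnames as `counts`.
#' @export
log_cpm <- function(counts, prior_count = 0.5, lib_size = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0, na.rm = TRUE)) stop("counts must be nonnegative")
  if (prior_count < 0) stop("'prior_count' must be >= 0")
  if (is.null(lib_size)) lib_size <- colSums(counts, na.rm = TRUE)
  if (any(lib_size <= 0)) stop("library sizes must be > 0")
  log2(sweep(counts + prior_count, 2, lib_size + 2 * prior_count, "/") * 1e6)
}
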