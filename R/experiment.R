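#' Construct a rhythm experiment
#'
#' Bundles a feature-by-sample measurement matrix with per-sample collection
#' times and the assumed rhythm period. Measurements are log-scale by
#' convention (e.g. log2-CPM, log2 microarray intensity); raw counts may be
#' stored by setting `is_counts = TRUE`, in which case [rhythmfit()] applies
#' CPM filtering, zero-count imputation and a log2-CPM transform (or voom)
#' before fitting.
#'
#' @param measurements Numeric matrix, features in rows, samples in columns.
#'   Row names are used as feature ids (generated if absent); column names as
#'   sample ids.
#' @param time Numeric vector of sample collection times in hours, one per
#'   column. Times may be negative or exceed the period; they are reduced
#'   modulo `period` during fitting. Duplicate times (replicates) are allowed.
#' @param period Assumed rhythm period tau in hours (default 24).
#' @param covariates Optional data.frame of per-sample covariates (one row per
#'   sample) entering the linear models additively, e.g. batch.
#' @param is_counts Logical; `TRUE` marks `measurements` as raw counts not yet
#'   log-transformed.
#'
#' @return An object of class `"rhythm_experiment"`: a list with elements
#'   `measurements`, `feature_ids`, `sample_ids`, `time`, `period`,
#'   `covariates`, `is_counts`.
#' @examples
#' t <- seq(0, 46, by = 2)
#' y <- rbind(gene1 = 5 + 2 * cos(2 * pi * t / 24))
#' ex <- rhythm_experiment(y, time = t)
#' @export
rhythm_experiment <- function(measurements, time, period = 24, covariates = NULL,
                              is_counts = FALSE) {
  measurements <- as.matrix(measurements)
  if (!is.numeric(measurements)) stop("'measurements' must be numeric")
  if (ncol(measurements) != length(time))
    stop("length(time) [", length(time), "] != ncol(measurements) [",
         ncol(measurements), "]")
  if (!all(is.finite(time))) stop("all sample times must be finite")
  if (!is.numeric(period) || length(period) != 1L || !is.finite(period) || period <= 0)
    stop("'period' must be a positive number")
  if (is.null(rownames(measurements)))
    rownames(measurements) <- paste0("feature_", seq_len(nrow(measurements)))
  if (is.null(colnames(measurements)))
    colnames(measurements) <- paste0("sample_", seq_len(ncol(measurements)))
  if (anyDuplicated(rownames(measurements)))
    stop("feature ids must be unique")
  if (anyDuplicated(colnames(measurements)))
    stop("sample ids must be unique")
  all_na <- rowSums(!is.na(measurements)) == 0L
  if (any(all_na))
    stop("feature(s) with no non-missing values: ",
         paste(head(rownames(measurements)[all_na], 5), collapse = ", "))
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != ncol(measurements))
      stop("'covariates' must have one row per sample")
  }
  structure(
    list(measurements = measurements,
         feature_ids = rownames(measurements),
         sample_ids = colnames(measurements),
         time = as.numeric(time),
         period = period,
         covariates = covariates,
         is_counts = isTRUE(is_counts)),
    class = "rhythm_experiment")
}

#' @export
print.rhythm_experiment <- function(x, ...) {
  cat("rhythm_experiment: ", nrow(x$measurements), " features x ",
      ncol(x$measurements), " samples\n", sep = "")
  cat("  period: ", x$period, " h; times: ",
    paste(format(range(x$time)), collapse = " to "), " h (",
    length(unique(x$time %% x$period)), " unique mod period)\n", sep = "")
  cat("  measurements: ", if (x$is_counts) "raw counts" else "log scale", "\n", sep = "")
  if (!is.null(x$covariates))
    cat("  covariates: ", paste(names(x$covariates), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.rhythm_experiment <- function(x) dim(x$measurements)

#' Read an experiment from delimited text files
#'
#' Reads a feature-by-sample expression matrix (first column = feature id,
#' remaining columns = samples) and a sample metadata table with columns
#' `sample_id` and `time` (hours) plus optional covariate columns. Samples are
#' matched by id; metadata rows without a matching column are an error.
#'
#' @param matrix_path Path to the TSV/CSV expression matrix.
#' @param metadata_path Path to the TSV/CSV sample metadata.
#' @param period Rhythm period in hours.
#' @param is_counts Whether the matrix holds raw counts.
#' @param sep Field separator; `NULL` (default) infers from the file extension
#'   (`.csv` = comma, otherwise tab).
#' @return A [rhythm_experiment()].
#' @export
read_experiment <- function(matrix_path, metadata_path, period = 24,
                            is_counts = FALSE, sep = NULL) {
  read1 <- function(path) {
    s <- if (!is.null(sep)) sep else if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    utils::read.table(path, header = TRUE, sep = s, check.names = FALSE,
                      stringsAsFactors = FALSE, quote = "\"", comment.char = "")
  }
  mat_df <- read1(matrix_path)
  meta <- read1(metadata_path)
  if (!all(c("sample_id", "time") %in% names(meta)))
    stop("metadata must contain columns 'sample_id' and 'time'")
  mat <- as.matrix(mat_df[, -1, drop = FALSE])
  rownames(mat) <- as.character(mat_df[[1]])
  missing <- setdiff(meta$sample_id, colnames(mat))
  if (length(missing))
    stop("metadata samples absent from matrix: ", paste(missing, collapse = ", "))
  mat <- mat[, as.character(meta$sample_id), drop = FALSE]
  cov_cols <- setdiff(names(meta), c("sample_id", "time"))
  covariates <- if (length(cov_cols)) meta[, cov_cols, drop = FALSE] else NULL
  rhythm_experiment(mat, time = meta$time, period = period,
                    covariates = covariates, is_counts = is_counts)
}

#' Write an experiment to delimited text files
#'
#' Writes the matrix and metadata in the same layout [read_experiment()]
#' consumes.
#'
#' @param experiment A [rhythm_experiment()].
#' @param matrix_path,metadata_path Output paths (tab-separated).
#' @return Invisibly, the experiment.
#' @export
write_experiment <- function(experiment, matrix_path, metadata_path) {
  stopifnot(inherits(experiment, "rhythm_experiment"))
  df <- data.frame(feature_id = experiment$feature_ids,
                   experiment$measurements, check.names = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- data.frame(sample_id = experiment$sample_ids, time = experiment$time)
  if (!is.null(experiment$covariates)) meta <- cbind(meta, experiment$covariates)
  utils::write.table(meta, metadata_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(experiment)
}
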