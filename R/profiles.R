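#' Community profile of one sample
#'
#' Relative abundances of one sample over integer T-RF bins (bp labels).
#'
#' @param sample_id sample identifier.
#' @param time_days days since the first sample.
#' @param abundances named numeric vector; names are integer bin labels (bp),
#'   values are relative-abundance fractions.
#' @param normalized if `TRUE` (default), require the abundances to sum to 1
#'   within 1e-9.
#' @return an object of class `community_profile`.
#' @export
community_profile <- function(sample_id, time_days, abundances, normalized = TRUE) {
  .check(length(abundances) >= 1, "profile %s has no bins", sample_id)
  .check(!is.null(names(abundances)), "abundances must be named by bin label")
  bins <- suppressWarnings(as.numeric(names(abundances)))
  .check(!anyNA(bins), "bin labels must be numeric bp values")
  .check(all(abundances >= 0), "abundances must be non-negative")
  if (normalized) {
    .check(abs(sum(abundances) - 1) < 1e-9,
           "profile %s abundances sum to %.12f, not 1", sample_id, sum(abundances))
  }
  o <- order(bins)
  structure(list(sample_id = as.character(sample_id),
                 time_days = as.numeric(time_days),
                 abundances = abundances[o]),
            class = "community_profile")
}

#' @export
print.community_profile <- function(x, ...) {
  cat(sprintf("community profile %s (day %g): %d T-RFs\n",
              x$sample_id, x$time_days, length(x$abundances)))
  print(round(x$abundances, 4))
  invisible(x)
}

#' Time-ordered series of community profiles
#'
#' The matrix view used by all downstream statistics: rows are samples in
#' strictly increasing time order, columns are the sorted union of T-RF bin
#' labels, entries are relative abundances with 0 for bins absent from a
#' sample.
#'
#' @param mat numeric samples x bins matrix; rownames are sample ids,
#'   colnames are bin labels (bp).
#' @param time_days numeric vector of days since the first sample, one per
#'   row, strictly increasing.
#' @return an object of class `profile_series` with fields `matrix`,
#'   `time_days`, `sample_ids`, `bins`.
#' @export
profile_series <- function(mat, time_days) {
  mat <- as.matrix(mat)
  .check(nrow(mat) == length(time_days),
         "time_days length (%d) != number of samples (%d)",
         length(time_days), nrow(mat))
  .check(!is.null(rownames(mat)), "matrix must carry sample ids as rownames")
  .check(anyDuplicated(rownames(mat)) == 0, "duplicate sample ids: %s",
         paste(unique(rownames(mat)[duplicated(rownames(mat))]), collapse = ", "))
  o <- order(time_days)
  mat <- mat[o, , drop = FALSE]
  time_days <- time_days[o]
  .check(all(diff(time_days) > 0), "time_days must be strictly increasing")
  bins <- suppressWarnings(as.numeric(colnames(mat)))
  .check(!anyNA(bins), "column names must be numeric bin labels")
  ob <- order(bins)
  structure(list(matrix = mat[, ob, drop = FALSE],
                 time_days = as.numeric(time_days),
                 sample_ids = rownames(mat),
                 bins = bins[ob]),
            class = "profile_series")
}

#' @export
print.profile_series <- function(x, ...) {
  cat(sprintf("profile series: %d samples (day %g-%g), %d T-RF bins (%s bp)\n",
              length(x$sample_ids), min(x$time_days), max(x$time_days),
              length(x$bins), paste(x$bins, collapse = ", ")))
  invisible(x)
}

#' @export
as.matrix.profile_series <- function(x, ...) x$matrix

#' Number of samples in a profile series
#' @param series a `profile_series`.
#' @return integer count.
#' @export
n_samples <- function(series) length(series$sample_ids)

#' Write / read a profile matrix as TSV
#'
#' Rows are samples (first columns `sample_id`, `time_days`), remaining
#' columns are bin labels.
#'
#' @param series a `profile_series`.
#' @param path output TSV path.
#' @return `path`, invisibly (`write_profile_series`); a `profile_series`
#'   (`read_profile_series`).
#' @export
write_profile_series <- function(series, path) {
  df <- data.frame(sample_id = series$sample_ids,
                   time_days = series$time_days,
                   series$matrix, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile_series
#' @export
read_profile_series <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  .check(all(c("sample_id", "time_days") %in% names(df)),
         "profile TSV needs sample_id and time_days columns")
  mat <- as.matrix(df[, setdiff(names(df), c("sample_id", "time_days")), drop = FALSE])
  rownames(mat) <- df$sample_id
  profile_series(mat, df$time_days)
}
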