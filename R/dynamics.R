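#' Pearson similarity between two community profiles (percent)
#'
#' The Pearson product-moment correlation between the two relative-abundance
#' vectors, expressed over the union of the bins of both profiles (absent
#' bins count as 0), multiplied by 100.
#'
#' @param a,b [community_profile()] objects.
#' @return similarity percentage in [-100, 100].
#' @export
pearson_similarity <- function(a, b) {
  .check(inherits(a, "community_profile") && inherits(b, "community_profile"),
         "inputs must be community_profile objects")
  bins <- sort(unique(c(names(a$abundances), names(b$abundances))))
  .check(length(bins) >= 2, "need >= 2 bins in the union to correlate")
  va <- vb <- stats::setNames(numeric(length(bins)), bins)
  va[names(a$abundances)] <- a$abundances
  vb[names(b$abundances)] <- b$abundances
  .pearson_pct(va, vb, a$sample_id, b$sample_id)
}

.pearson_pct <- function(va, vb, id_a = "a", id_b = "b") {
  if (stats::var(va) == 0) {
    stop(sprintf("profile %s is constant across bins: Pearson correlation undefined", id_a),
         call. = FALSE)
  }
  if (stats::var(vb) == 0) {
    stop(sprintf("profile %s is constant across bins: Pearson correlation undefined", id_b),
         call. = FALSE)
  }
  100 * stats::cor(va, vb)
}

#' All pairwise Pearson similarities of a profile series
#'
#' @param series a [profile_series()] with >= 2 samples.
#' @return a symmetric `similarity_matrix` (percent) with 100 on the
#'   diagonal.
#' @export
similarity_matrix <- function(series) {
  .check(inherits(series, "profile_series"), "series must be a profile_series")
  n <- n_samples(series)
  .check(n >= 2, "need >= 2 samples")
  .check(ncol(series$matrix) >= 2, "need >= 2 bins")
  const <- which(apply(series$matrix, 1, stats::var) == 0)
  .check(length(const) == 0,
         "constant profile(s), Pearson undefined: %s",
         paste(series$sample_ids[const], collapse = ", "))
  S <- 100 * stats::cor(t(series$matrix))
  diag(S) <- 100
  dimnames(S) <- list(series$sample_ids, series$sample_ids)
  structure(S, class = c("similarity_matrix", "matrix"))
}

#' Moving-window community change analysis
#'
#' For each pair of consecutive sampling dates the change value is
#' `100 - Pearson similarity (percent)` between the two profiles. The
#' summary statistic delta-t is the arithmetic mean and sample (n-1)
#' standard deviation of the change values, optionally restricted to pairs
#' whose later date falls after `exclude_before_day` (e.g. to drop a reactor
#' start-up phase). Consecutive means adjacent in the time-sorted series
#' even if the actual gap differs from the nominal interval; the realized
#' gap is recorded per pair.
#'
#' Negative correlations give change values above 100%; they are reported
#' unclamped, with a warning, since the change-percentage framing presumes
#' non-negative correlation.
#'
#' @param series a [profile_series()] with >= 2 samples.
#' @param exclude_before_day drop pairs whose later day is <= this value
#'   from the delta-t summary (`NULL` keeps all pairs).
#' @return a `change_series` object: data.frame fields `pair_end_day`,
#'   `gap_days`, `change_percent`, `included`, plus `delta_t_mean`,
#'   `delta_t_sd`, `n_pairs_used`, `excluded_range`.
#' @export
moving_window <- function(series, exclude_before_day = NULL) {
  .check(inherits(series, "profile_series"), "series must be a profile_series")
  n <- n_samples(series)
  .check(n >= 2, "need >= 2 samples for consecutive pairs")
  S <- similarity_matrix(series)
  idx <- seq_len(n - 1L)
  sim <- S[cbind(idx, idx + 1L)]
  change <- 100 - sim
  if (any(sim < 0)) {
    warning(sprintf("%d consecutive pair(s) have negative Pearson correlation; change values exceed 100%% and are not clamped",
                    sum(sim < 0)), call. = FALSE)
  }
  end_day <- series$time_days[idx + 1L]
  included <- if (is.null(exclude_before_day)) rep(TRUE, n - 1L) else
    end_day > exclude_before_day
  used <- change[included]
  delta_mean <- if (length(used) >= 1) mean(used) else NA_real_
  delta_sd <- if (length(used) >= 2) stats::sd(used) else NA_real_
  if (length(used) < 2) {
    message("fewer than 2 retained pairs: delta-t sd is undefined and reported as NA")
  }
  structure(list(
    pairs = data.frame(pair_end_day = end_day,
                       gap_days = diff(series$time_days),
                       change_percent = change,
                       included = included),
    delta_t_mean = delta_mean,
    delta_t_sd = delta_sd,
    n_pairs_used = length(used),
    excluded_range = if (is.null(exclude_before_day)) NULL else
      c(series$time_days[1L], exclude_before_day)
  ), class = "change_series")
}

#' @export
print.change_series <- function(x, ...) {
  cat(sprintf("moving-window change series: %d consecutive pairs (%d used)\n",
              nrow(x$pairs), x$n_pairs_used))
  if (!is.null(x$excluded_range)) {
    cat(sprintf("  pairs ending on or before day %g excluded\n", x$excluded_range[2]))
  }
  cat(sprintf("  delta-t = %.1f%% +/- %s%%\n", x$delta_t_mean,
              if (is.na(x$delta_t_sd)) "NA" else sprintf("%.1f", x$delta_t_sd)))
  invisible(x)
}

#' Write a change series as TSV plus a JSON summary
#'
#' @param x a `change_series`.
#' @param tsv_path per-pair table (pair_end_day, gap_days, change_percent,
#'   included).
#' @param json_path summary (delta_t_mean, delta_t_sd, n_pairs_used,
#'   excluded_range).
#' @return invisibly, `tsv_path`.
#' @export
write_change_series <- function(x, tsv_path, json_path) {
  utils::write.table(x$pairs, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(delta_t_mean = x$delta_t_mean, delta_t_sd = x$delta_t_sd,
         n_pairs_used = x$n_pairs_used,
         excluded_range = x$excluded_range),
    json_path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(tsv_path)
}
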