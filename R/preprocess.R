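#' Read a fragment-analysis peak table
#'
#' Expects a CSV with header columns `sample_id`, `time_days`,
#' `fragment_length`, `area`; extra columns are ignored. Malformed rows
#' (non-numeric or non-positive fragment length, missing or negative area)
#' are reported by data row number.
#'
#' @param path CSV file path.
#' @return peak table data.frame with the four canonical columns.
#' @export
read_peak_table <- function(path) {
  .check(file.exists(path), "peak table not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "time_days", "fragment_length", "area")
  miss <- setdiff(need, names(df))
  .check(length(miss) == 0, "peak table %s is missing required column(s): %s",
         path, paste(miss, collapse = ", "))
  df <- df[, need]
  df$fragment_length <- suppressWarnings(as.numeric(df$fragment_length))
  df$area <- suppressWarnings(as.numeric(df$area))
  bad <- which(is.na(df$fragment_length) | df$fragment_length <= 0 |
                 is.na(df$area) | df$area < 0)
  .check(length(bad) == 0,
         "malformed peak rows (non-positive/missing length or negative/missing area) at data row(s): %s",
         paste(utils::head(bad, 10), collapse = ", "))
  df
}

#' Restrict peaks to the analyzable size window
#'
#' Terminal fragments shorter than `min_bp` or longer than `max_bp` are
#' excluded (to avoid primer detection and sizing uncertainty at the ends of
#' the standard curve); the boundaries themselves are retained.
#'
#' @param peaks peak table data.frame.
#' @param min_bp,max_bp window bounds in bp (defaults 50 and 500).
#' @return filtered peak table.
#' @export
filter_size_window <- function(peaks, min_bp = 50, max_bp = 500) {
  .check(min_bp < max_bp, "min_bp (%g) must be < max_bp (%g)", min_bp, max_bp)
  peaks[peaks$fragment_length >= min_bp & peaks$fragment_length <= max_bp, ,
        drop = FALSE]
}

#' Align peaks across samples into integer T-RF bins
#'
#' Fragment lengths from all samples are clustered by single linkage in one
#' dimension: sorted lengths are chained together wherever the gap to the
#' next length is strictly below `tolerance_bp` (so labels a full tolerance
#' apart stay separate, and re-binning already-binned integer labels is a
#' no-op). Each cluster is labelled with the rounded area-weighted mean
#' length, and within a sample the areas of peaks falling in one cluster are
#' summed. The default tolerance of 1 bp reflects typical capillary sizing
#' precision.
#'
#' @param peaks size-filtered peak table.
#' @param tolerance_bp single-linkage threshold in bp.
#' @return peak table with `fragment_length` replaced by integer bin labels,
#'   one row per (sample, bin).
#' @export
bin_trfs <- function(peaks, tolerance_bp = 1.0) {
  .check(tolerance_bp >= 0, "tolerance_bp must be >= 0")
  if (nrow(peaks) == 0) return(peaks)
  o <- order(peaks$fragment_length)
  len <- peaks$fragment_length[o]
  # single-linkage chains: a new cluster starts where the gap reaches the link
  cluster <- cumsum(c(1, diff(len) >= tolerance_bp))[order(o)]
  label <- vapply(split(seq_len(nrow(peaks)), cluster), function(i) {
    round(stats::weighted.mean(peaks$fragment_length[i], peaks$area[i]))
  }, numeric(1))
  binned <- stats::aggregate(
    area ~ sample_id + time_days + fragment_length,
    data = data.frame(sample_id = peaks$sample_id,
                      time_days = peaks$time_days,
                      fragment_length = label[as.character(cluster)],
                      area = peaks$area),
    FUN = sum)
  binned <- binned[order(binned$sample_id, binned$fragment_length), ]
  rownames(binned) <- NULL
  binned[, c("sample_id", "time_days", "fragment_length", "area")]
}

#' Convert binned peak areas to relative abundances
#'
#' Per sample, each bin's relative abundance is the ratio of its peak area to
#' the total area of all peaks in that sample.
#'
#' @param peaks binned peak table.
#' @return list of [community_profile()] objects, one per sample.
#' @export
relative_abundance <- function(peaks) {
  .check(nrow(peaks) > 0, "empty peak table")
  split_idx <- split(seq_len(nrow(peaks)), peaks$sample_id)
  lapply(split_idx, function(i) {
    total <- sum(peaks$area[i])
    .check(total > 0, "sample %s has zero total peak area", peaks$sample_id[i[1]])
    ab <- peaks$area[i] / total
    names(ab) <- as.character(peaks$fragment_length[i])
    community_profile(peaks$sample_id[i[1]], peaks$time_days[i[1]], ab)
  })
}

#' Remove background-noise T-RFs below the abundance floor
#'
#' Bins with relative abundance strictly below `floor` (default 2%) are
#' regarded as background noise and excluded. With `renormalize = TRUE`
#' (default) the remaining abundances are rescaled to sum to 1, keeping the
#' profile a composition for correlation and ordination; with `FALSE` the raw
#' ratios are retained for reporting. The removed mass is attached as
#' attribute `removed_mass`.
#'
#' @param profile a [community_profile()].
#' @param floor relative-abundance noise floor (fraction).
#' @param renormalize rescale retained bins to sum to 1?
#' @return filtered `community_profile` with attribute `removed_mass`.
#' @export
filter_noise <- function(profile, floor = 0.02, renormalize = TRUE) {
  .check(inherits(profile, "community_profile"), "profile must be a community_profile")
  ab <- profile$abundances
  keep <- ab >= floor  # strictly-below-floor bins are noise; the floor itself survives
  .check(any(keep), "sample %s: every T-RF is below the %.3f noise floor",
         profile$sample_id, floor)
  removed <- sum(ab[!keep])
  kept <- ab[keep]
  if (renormalize) kept <- kept / sum(kept)
  out <- community_profile(profile$sample_id, profile$time_days, kept,
                           normalized = renormalize)
  attr(out, "removed_mass") <- removed
  out
}

#' Read the operational/environmental covariate table
#'
#' CSV with `sample_id`, `time_days` and named covariate columns (the
#' activated-sludge roster: influent/effluent BOD and ammonia, effluent
#' nitrite and nitrate, ammonia removal efficiency, DO, temperature, SVI,
#' MLSS, SRT). Empty cells become `NA` and are never imputed. Negative
#' concentrations or removal efficiencies outside [0, 100] are rejected.
#'
#' @param path CSV file path.
#' @return covariate data.frame.
#' @export
read_env_table <- function(path) {
  .check(file.exists(path), "covariate table not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  .check(all(c("sample_id", "time_days") %in% names(df)),
         "covariate table needs sample_id and time_days columns")
  num_cols <- setdiff(names(df), "sample_id")
  for (v in num_cols) df[[v]] <- suppressWarnings(as.numeric(df[[v]]))
  conc <- intersect(c("influent_BOD", "effluent_BOD", "influent_NH3", "effluent_NH3",
                      "effluent_NO2", "effluent_NO3", "DO", "SVI", "MLSS", "SRT"),
                    names(df))
  for (v in conc) .check(all(df[[v]] >= 0, na.rm = TRUE), "%s has negative values", v)
  if ("NH3_removal_eff" %in% names(df)) {
    .check(all(df$NH3_removal_eff >= 0 & df$NH3_removal_eff <= 100, na.rm = TRUE),
           "NH3_removal_eff must lie in [0, 100]")
  }
  if (anyNA(df[num_cols])) {
    nmiss <- sum(is.na(df[num_cols]))
    message(sprintf("covariate table: %d missing value(s) flagged (not imputed)", nmiss))
  }
  df
}

#' Assemble filtered profiles and covariates into aligned series
#'
#' Profiles are ordered by time, their bins unioned with explicit zeros for
#' absent bins, and the covariate rows aligned to the same sample order.
#'
#' @param profiles list of [community_profile()] objects.
#' @param env covariate data.frame with a `sample_id` column covering the
#'   same samples.
#' @return list with `series` (a [profile_series()]) and `env` (covariates
#'   reordered to match).
#' @export
assemble_series <- function(profiles, env) {
  ids <- vapply(profiles, `[[`, character(1), "sample_id")
  only_prof <- setdiff(ids, env$sample_id)
  only_env <- setdiff(env$sample_id, ids)
  .check(length(only_prof) == 0 && length(only_env) == 0,
         "sample id mismatch: %s%s",
         if (length(only_prof)) paste0("missing from env: ",
                                       paste(only_prof, collapse = ", ")) else "",
         if (length(only_env)) paste0(" missing from profiles: ",
                                      paste(only_env, collapse = ", ")) else "")
  bins <- sort(unique(unlist(lapply(profiles, function(p) names(p$abundances)))))
  mat <- matrix(0, length(profiles), length(bins), dimnames = list(ids, bins))
  for (i in seq_along(profiles)) {
    mat[i, names(profiles[[i]]$abundances)] <- profiles[[i]]$abundances
  }
  series <- profile_series(mat, vapply(profiles, `[[`, numeric(1), "time_days"))
  list(series = series,
       env = env[match(series$sample_ids, env$sample_id), , drop = FALSE])
}

#' Full preprocessing pipeline: raw peaks to aligned profile series
#'
#' Applies, in order: the 50-500 bp size window, single-linkage T-RF binning,
#' relative-abundance conversion, the 2% noise floor, and series assembly
#' against the covariate table.
#'
#' @param peaks raw peak table (from [read_peak_table()] or
#'   [render_peak_tables()]).
#' @param env covariate data.frame.
#' @param min_bp,max_bp size window (bp).
#' @param tolerance_bp binning tolerance (bp).
#' @param floor noise floor (fraction).
#' @param renormalize renormalize after noise filtering?
#' @return list with `series`, `env`, and `removed_mass` (named per sample).
#' @export
preprocess_peaks <- function(peaks, env, min_bp = 50, max_bp = 500,
                             tolerance_bp = 1.0, floor = 0.02,
                             renormalize = TRUE) {
  peaks <- filter_size_window(peaks, min_bp, max_bp)
  peaks <- bin_trfs(peaks, tolerance_bp)
  profiles <- relative_abundance(peaks)
  profiles <- lapply(profiles, filter_noise, floor = floor, renormalize = renormalize)
  removed <- vapply(profiles, attr, numeric(1), "removed_mass")
  out <- assemble_series(profiles, env)
  out$removed_mass <- removed
  out
}
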