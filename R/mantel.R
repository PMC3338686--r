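#' Community distance matrix from a profile series
#'
#' Pairwise distances between samples on their relative-abundance vectors.
#' `"bray-curtis"` (the ecological default) is computed with
#' [vegan::vegdist()]; `"one-minus-pearson"` is `1 - r` on the aligned bin
#' vectors, consistent with the moving-window similarity.
#'
#' @param series a [profile_series()] with >= 3 samples.
#' @param metric `"bray-curtis"` or `"one-minus-pearson"`.
#' @return a `dist_matrix` object: symmetric matrix with zero diagonal and
#'   attribute `metric`.
#' @export
community_distance <- function(series, metric = c("bray-curtis", "one-minus-pearson")) {
  metric <- tryCatch(match.arg(metric), error = function(e)
    stop(sprintf("unknown metric '%s'; options: bray-curtis, one-minus-pearson",
                 metric[1]), call. = FALSE))
  .check(inherits(series, "profile_series"), "series must be a profile_series")
  .check(n_samples(series) >= 3, "need >= 3 samples for a distance matrix")
  D <- switch(metric,
    "bray-curtis" = as.matrix(vegan::vegdist(series$matrix, method = "bray")),
    "one-minus-pearson" = 1 - stats::cor(t(series$matrix)))
  diag(D) <- 0
  dimnames(D) <- list(series$sample_ids, series$sample_ids)
  structure(D, metric = metric, class = c("dist_matrix", "matrix"))
}

#' Per-variable environmental distance matrix
#'
#' Distance between samples `i` and `j` is `|x_i - x_j|` on the (optionally
#' z-scored) covariate. Samples with a missing value are dropped
#' (complete-case per variable) and their ids recorded in attribute
#' `dropped`.
#'
#' @param env covariate data.frame with `sample_id`.
#' @param variable covariate column name.
#' @param standardize z-score the variable first (default `TRUE`; the Mantel
#'   correlation is invariant to this, but it keeps distances comparable
#'   across variables).
#' @return a `dist_matrix` with attributes `metric`, `variable`, `dropped`.
#' @export
variable_distance <- function(env, variable, standardize = TRUE) {
  .check(variable %in% names(env), "variable '%s' not in covariate table", variable)
  x <- env[[variable]]
  ok <- !is.na(x)
  .check(sum(ok) >= 3, "variable '%s' has fewer than 3 non-missing values", variable)
  dropped <- env$sample_id[!ok]
  if (length(dropped) > 0) {
    message(sprintf("variable %s: dropping sample(s) with missing values: %s",
                    variable, paste(dropped, collapse = ", ")))
  }
  x <- x[ok]
  if (standardize) {
    s <- stats::sd(x)
    x <- if (s > 0) (x - mean(x)) / s else x - mean(x)
  }
  D <- abs(outer(x, x, "-"))
  ids <- env$sample_id[ok]
  dimnames(D) <- list(ids, ids)
  structure(D, metric = "abs-diff", variable = variable, dropped = dropped,
            class = c("dist_matrix", "matrix"))
}

# all permutations of 1..n (n <= 7 guarded by the caller)
.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    rest <- seq_len(n)[-k]
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub), n - 1L)))
  }
  out
}

#' Mantel test between two distance matrices
#'
#' The Mantel statistic `r_M` is the Pearson correlation between the
#' corresponding upper-triangle entries of the two matrices. The null
#' distribution is built by jointly permuting the rows and columns of `Dy`;
#' in `"sampled"` mode `P = (1 + b) / (1 + n_perm)` where `b` counts null
#' statistics at least as extreme as the observed one, and in
#' `"exhaustive"` mode (n <= 7) all `n!` relabelings are enumerated and `P`
#' is the exact fraction at least as extreme (the identity relabeling makes
#' P strictly positive). `tail = "greater"` (default) tests for positive
#' association; `"two-sided"` compares `|r|`.
#'
#' @param Dx,Dy `dist_matrix` objects (or plain symmetric matrices) with
#'   matching labels in matching order.
#' @param n_perm permutations in sampled mode (default 999).
#' @param seed integer seed for sampled mode.
#' @param tail `"greater"` or `"two-sided"`.
#' @param mode `"sampled"` or `"exhaustive"`.
#' @return a `mantel_result`: `r_m`, `p_value`, `n_perm` (or `NA` with
#'   `exhaustive = TRUE`), `tail`, `n` (samples), `metrics`.
#' @export
mantel_test <- function(Dx, Dy, n_perm = 999, seed = NULL,
                        tail = c("greater", "two-sided"),
                        mode = c("sampled", "exhaustive")) {
  tail <- match.arg(tail)
  mode <- match.arg(mode)
  Dx <- as.matrix(Dx); Dy <- as.matrix(Dy)
  .check(!is.null(rownames(Dx)) && !is.null(rownames(Dy)),
         "distance matrices must carry sample labels")
  if (!identical(rownames(Dx), rownames(Dy))) {
    diffs <- c(setdiff(rownames(Dx), rownames(Dy)),
               setdiff(rownames(Dy), rownames(Dx)))
    .check(length(diffs) == 0,
           "label mismatch between matrices: %s", paste(diffs, collapse = ", "))
    Dy <- Dy[rownames(Dx), rownames(Dx)]  # same set, different order: realign
  }
  n <- nrow(Dx)
  .check(n >= 4, "Mantel test needs >= 4 samples")
  tri <- upper.tri(Dx)
  x <- Dx[tri]; y <- Dy[tri]
  .check(stats::var(x) > 0 && stats::var(y) > 0,
         "zero variance in a distance triangle: Mantel correlation undefined")
  xc <- x - mean(x)
  ssx <- sum(xc^2)
  cor0 <- function(yv) {
    yc <- yv - mean(yv)
    sum(xc * yc) / sqrt(ssx * sum(yc^2))
  }
  r_obs <- cor0(y)
  ri <- row(Dx)[tri]; ci <- col(Dx)[tri]
  extreme <- function(r) if (tail == "greater") r >= r_obs else abs(r) >= abs(r_obs)

  if (mode == "exhaustive") {
    .check(n <= 7, "exhaustive enumeration limited to n <= 7 (n! relabelings)")
    perms <- .permutations(n)
    rs <- apply(perms, 1, function(p) cor0(Dy[cbind(p[ri], p[ci])]))
    p_val <- mean(extreme(rs))
    n_perm_out <- NA_integer_; exhaustive <- TRUE
  } else {
    .check(n_perm >= 1, "n_perm must be >= 1")
    b <- 0L
    with_seed(seed, {
      for (k in seq_len(n_perm)) {
        p <- sample.int(n)
        if (extreme(cor0(Dy[cbind(p[ri], p[ci])]))) b <- b + 1L
      }
    })
    p_val <- (1 + b) / (1 + n_perm)
    n_perm_out <- as.integer(n_perm); exhaustive <- FALSE
  }
  structure(list(r_m = r_obs, p_value = p_val, n_perm = n_perm_out,
                 exhaustive = exhaustive, tail = tail, n = n,
                 metrics = c(attr(Dx, "metric") %||% "unknown",
                             attr(Dy, "metric") %||% "unknown")),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test (%s, %s): r_M = %.3f, P = %.4g (n = %d, %s)\n",
              paste(x$metrics, collapse = " vs "), x$tail, x$r_m, x$p_value, x$n,
              if (x$exhaustive) "exhaustive" else sprintf("%d permutations", x$n_perm)))
  invisible(x)
}

#' Per-variable Mantel table
#'
#' Runs [mantel_test()] between the community distance matrix and the
#' distance matrix of each covariate, reproducing the one-row-per-variable
#' layout of a variable-screening table. Complete-case handling is per
#' variable: samples missing a covariate are dropped from both matrices for
#' that row.
#'
#' @param series a [profile_series()].
#' @param env covariate data.frame aligned with the series.
#' @param variables covariate columns to test (default: all numeric columns
#'   except `time_days`).
#' @param metric community distance metric (see [community_distance()]).
#' @param n_perm,seed,tail passed to [mantel_test()].
#' @return data.frame with `variable`, `r_m`, `p_value`, `n_used`.
#' @export
mantel_table <- function(series, env, variables = NULL,
                         metric = "bray-curtis", n_perm = 999, seed = NULL,
                         tail = "greater") {
  if (is.null(variables)) {
    variables <- setdiff(names(env)[vapply(env, is.numeric, logical(1))],
                         "time_days")
  }
  Dc_full <- community_distance(series, metric)
  seeds <- .sub_seeds(seed %||% 1L, length(variables))
  rows <- vector("list", length(variables))
  for (i in seq_along(variables)) {
    v <- variables[i]
    Dv <- variable_distance(env, v)
    ids <- rownames(Dv)
    Dc <- structure(Dc_full[ids, ids], metric = attr(Dc_full, "metric"),
                    class = c("dist_matrix", "matrix"))
    mt <- mantel_test(Dc, Dv, n_perm = n_perm, seed = seeds[i], tail = tail)
    rows[[i]] <- data.frame(variable = v, r_m = mt$r_m, p_value = mt$p_value,
                            n_used = mt$n, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
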