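#' Simulate the covariate table of a scenario
#'
#' Each covariate follows a stationary Gaussian AR(1) process
#' `x_t = mean + rho * (x_{t-1} - mean) + e_t`, with the innovation sd chosen
#' as `sd * sqrt(1 - rho^2)` so the stationary sd equals the specified `sd`;
#' the first value is drawn from the stationary distribution. Values are
#' clamped to the variable's `[min, max]` range at each step (detection limits
#' and physical bounds; the default range is unbounded, in which case the
#' process is exactly the stationary AR(1)). Series are reproducible from
#' the scenario seed.
#'
#' @param scenario a [trflp_scenario()].
#' @return data.frame with `sample_id`, `time_days` and one column per
#'   covariate.
#' @export
simulate_env_series <- function(scenario) {
  .check(inherits(scenario, "trflp_scenario"), "scenario must be a trflp_scenario")
  specs <- scenario$env_specs
  .check(all(abs(specs$rho) < 1), "|rho| >= 1: non-stationary AR(1) rejected")
  n <- scenario$n_samples
  ids <- sprintf("S%02d", seq_len(n))
  env <- data.frame(sample_id = ids,
                    time_days = (seq_len(n) - 1) * scenario$interval_days,
                    stringsAsFactors = FALSE)
  seeds <- .sub_seeds(scenario$seed, nrow(specs) + 10L)
  lo <- specs$min %||% rep(-Inf, nrow(specs))
  hi <- specs$max %||% rep(Inf, nrow(specs))
  for (i in seq_len(nrow(specs))) {
    env[[specs$variable[i]]] <- with_seed(seeds[i], {
      .ar1(n, specs$mean[i], specs$sd[i], specs$rho[i], lo[i], hi[i])
    })
  }
  env
}

.ar1 <- function(n, mean, sd, rho, lo = -Inf, hi = Inf) {
  clamp <- function(v) pmin(pmax(v, lo), hi)
  if (sd == 0) return(rep(clamp(mean), n))
  x <- numeric(n)
  x[1] <- clamp(stats::rnorm(1, mean, sd))
  innov_sd <- sd * sqrt(1 - rho^2)
  e <- stats::rnorm(n - 1, 0, innov_sd)
  for (t in seq_len(n - 1)) x[t + 1] <- clamp(mean + rho * (x[t] - mean) + e[t])
  x
}

#' Simulate true community profiles from covariates
#'
#' Taxon `k` has expected unnormalized abundance
#' `a_kt = h_k * exp(-(x_t - u_k)^2 / (2 * t_k^2))` where `x_t` is its driver
#' covariate at time `t`; the profile at `t` is `a_.t` normalized to sum to 1.
#' Deterministic given the covariates, unless the scenario requests Dirichlet
#' resampling (`dirichlet_conc`), in which case each profile is redrawn as
#' `Dirichlet(conc * p)` to emulate compositional measurement noise.
#'
#' @param scenario a [trflp_scenario()].
#' @param env covariate table from [simulate_env_series()] (or measured data
#'   with the same columns); must contain every driver named in the scenario
#'   and `n_samples` rows.
#' @return a [profile_series()] over the scenario's T-RF bins.
#' @export
simulate_profile_series <- function(scenario, env) {
  .check(inherits(scenario, "trflp_scenario"), "scenario must be a trflp_scenario")
  resp <- scenario$response_specs
  missing_drv <- setdiff(unique(resp$driver), names(env))
  .check(length(missing_drv) == 0,
         "driver variable(s) missing from env: %s", paste(missing_drv, collapse = ", "))
  .check(nrow(env) == scenario$n_samples,
         "env has %d rows; scenario expects %d", nrow(env), scenario$n_samples)

  n <- nrow(env)
  A <- matrix(0, n, nrow(resp),
              dimnames = list(env$sample_id, as.character(resp$trf)))
  for (k in seq_len(nrow(resp))) {
    x <- env[[resp$driver[k]]]
    A[, k] <- resp$h[k] * exp(-(x - resp$optimum[k])^2 / (2 * resp$tolerance[k]^2))
  }
  P <- A / rowSums(A)
  if (!is.null(scenario$dirichlet_conc)) {
    seeds <- .sub_seeds(scenario$seed, 2L)
    P <- with_seed(seeds[2L], {
      t(apply(P, 1, function(p) {
        g <- stats::rgamma(length(p), shape = scenario$dirichlet_conc * p)
        g / sum(g)
      }))
    })
    colnames(P) <- as.character(resp$trf)
  }
  profile_series(P, env$time_days)
}

#' Render a profile series as raw fragment-analysis peak tables
#'
#' Each true taxon becomes one peak per sample with area
#' `relative abundance * total_area` and fragment length equal to its bin
#' label plus Gaussian sizing jitter. Noise peaks (count per
#' `scenario$n_noise_peaks`) are added at uniform random lengths in
#' [50, 500] bp, rejected within +/- 2 bp of any true bin, with areas drawn
#' so each noise peak's relative abundance stays strictly below
#' `scenario$max_noise_rel`. Reproducible from the scenario seed.
#'
#' @param series a normalized [profile_series()].
#' @param scenario the [trflp_scenario()] that produced it.
#' @return a peak table data.frame with columns `sample_id`, `time_days`,
#'   `fragment_length`, `area`.
#' @export
render_peak_tables <- function(series, scenario) {
  .check(inherits(series, "profile_series"), "series must be a profile_series")
  .check(all(abs(rowSums(series$matrix) - 1) < 1e-9), "series must be normalized")
  seeds <- .sub_seeds(scenario$seed, 5L)
  true_bins <- series$bins
  n <- n_samples(series)
  with_seed(seeds[3L], {
    out <- vector("list", n)
    for (i in seq_len(n)) {
      p <- series$matrix[i, ]
      keep <- p > 0
      lengths <- true_bins[keep] +
        if (scenario$length_jitter_sd > 0)
          stats::rnorm(sum(keep), 0, scenario$length_jitter_sd) else 0
      areas <- p[keep] * scenario$total_area
      if (scenario$n_noise_peaks > 0) {
        nl <- .noise_lengths(scenario$n_noise_peaks, true_bins)
        # areas relative to the true total; the final denominator only grows,
        # so each noise peak's realized relative abundance stays < max_noise_rel
        na <- stats::runif(scenario$n_noise_peaks, 0, scenario$max_noise_rel) *
          scenario$total_area
        lengths <- c(lengths, nl)
        areas <- c(areas, na)
      }
      out[[i]] <- data.frame(sample_id = series$sample_ids[i],
                             time_days = series$time_days[i],
                             fragment_length = lengths,
                             area = unname(areas),
                             stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
}

.noise_lengths <- function(k, true_bins) {
  res <- numeric(0)
  while (length(res) < k) {
    cand <- stats::runif(2L * k, 50, 500)
    ok <- vapply(cand, function(x) all(abs(x - true_bins) > 2), logical(1))
    res <- c(res, cand[ok])
  }
  res[seq_len(k)]
}

#' Construct a profile series with exact consecutive-pair correlation
#'
#' Builds `n_samples` compositional profiles over `n_bins` T-RF bins such
#' that the Pearson correlation between every pair of consecutive profiles
#' equals `target_r` to near machine precision. Profiles are generated as
#' points on a sphere in the centered simplex: each step rotates the previous
#' centered profile by the angle `acos(target_r)` in a random direction
#' orthogonal to it, so the cosine between consecutive centered profiles --
#' which Pearson correlation measures -- is exactly `target_r`. Used as the
#' analytic oracle for the moving-window change statistic: every change value
#' is then `100 * (1 - target_r)` percent.
#'
#' @param n_samples number of profiles (>= 2).
#' @param target_r desired consecutive Pearson correlation, in (-1, 1].
#' @param seed integer seed for the random rotation directions.
#' @param n_bins number of T-RF bins (>= 3; default 3).
#' @param interval_days spacing of the time axis (default 15).
#' @return a [profile_series()].
#' @export
fixed_similarity_series <- function(n_samples, target_r, seed = 1L,
                                    n_bins = 3L, interval_days = 15) {
  .check(n_samples >= 2, "n_samples must be >= 2")
  .check(n_bins >= 3, "need >= 3 bins for a rotation plane in the centered simplex")
  .check(target_r > -1 && target_r <= 1,
         "target_r must lie in (-1, 1]: a correlation of %.3f is infeasible", target_r)
  m <- as.integer(n_bins)
  # orthonormal basis of the subspace of R^m orthogonal to the all-ones vector
  B <- qr.Q(qr(cbind(rep(1, m), diag(m))))[, 2:m, drop = FALSE]
  theta <- acos(target_r)
  C <- matrix(0, n_samples, m - 1L)
  with_seed(seed, {
    v <- stats::rnorm(m - 1L)
    C[1L, ] <- v / sqrt(sum(v^2))
    for (t in seq_len(n_samples - 1L)) {
      prev <- C[t, ]
      if (m - 1L == 1L) {
        w <- 0 * prev  # no orthogonal direction in 1-D; theta must be 0
        .check(target_r == 1, "target_r < 1 infeasible with 2 effective dimensions")
      } else {
        w <- stats::rnorm(m - 1L)
        w <- w - sum(w * prev) * prev
        nw <- sqrt(sum(w^2))
        .check(nw > 1e-12, "degenerate rotation direction")
        w <- w / nw
      }
      nxt <- cos(theta) * prev + sin(theta) * w
      C[t + 1L, ] <- nxt / sqrt(sum(nxt^2))
    }
  })
  eps <- 0.9 / m  # keeps every entry of 1/m + eps * (B c) strictly positive
  P <- matrix(1 / m, n_samples, m) + eps * (C %*% t(B))
  bins <- if (m == 3L) c(219L, 354L, 491L) else seq(100L, by = 10L, length.out = m)
  dimnames(P) <- list(sprintf("S%02d", seq_len(n_samples)), as.character(bins))
  profile_series(P, (seq_len(n_samples) - 1) * interval_days)
}

#' Write scenario outputs in the pipeline's CSV dialects
#'
#' Writes the rendered peak table and the covariate table as the CSV files
#' the preprocessing stage reads.
#'
#' @param scenario a [trflp_scenario()].
#' @param peak_path,env_path output CSV paths.
#' @return invisibly, a list with the simulated `env`, true `series` and
#'   rendered `peaks`.
#' @export
write_synthetic_study <- function(scenario, peak_path, env_path) {
  env <- simulate_env_series(scenario)
  series <- simulate_profile_series(scenario, env)
  peaks <- render_peak_tables(series, scenario)
  utils::write.csv(peaks, peak_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(env, env_path, row.names = FALSE, quote = FALSE)
  invisible(list(env = env, series = series, peaks = peaks))
}
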