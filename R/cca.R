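#' Chi-square standardization of an abundance table
#'
#' The correspondence-analysis core: with `P = Y / grand total`, row sums
#' `r` and column sums `c` of `P`, the standardized residual matrix is
#' `Q[i, j] = (P[i, j] - r_i c_j) / sqrt(r_i c_j)`. The total chi-square
#' inertia of the table is `sum(Q^2)`.
#'
#' @param Y non-negative samples x bins matrix with no zero row or column
#'   sums.
#' @return list with `Q`, row weights `r`, column weights `c`, and
#'   `total_inertia`.
#' @export
chi_square_standardize <- function(Y) {
  Y <- as.matrix(Y)
  .check(all(Y >= 0), "Y must be non-negative")
  rs <- rowSums(Y); cs <- colSums(Y)
  zr <- which(rs == 0); zc <- which(cs == 0)
  .check(length(zr) == 0, "zero row sum(s): %s",
         paste(if (is.null(rownames(Y))) zr else rownames(Y)[zr], collapse = ", "))
  .check(length(zc) == 0, "zero column sum(s): %s",
         paste(if (is.null(colnames(Y))) zc else colnames(Y)[zc], collapse = ", "))
  tot <- sum(Y)
  P <- Y / tot
  r <- rs / tot
  c <- cs / tot
  E <- outer(r, c)
  Q <- (P - E) / sqrt(E)
  dimnames(Q) <- dimnames(Y)
  list(Q = Q, r = r, c = c, total_inertia = sum(Q^2))
}

# Weighted standardization of covariates: center and scale each column with
# row weights r, then multiply rows by sqrt(r) so ordinary least squares on
# the result is weighted least squares on the original. Constant columns are
# dropped with a warning; returns the sqrt-weighted design Xs.
.standardize_constraints <- function(X, r) {
  X <- as.matrix(X)
  .check(is.numeric(X), "constraint matrix X must be numeric")
  if (is.null(colnames(X))) colnames(X) <- paste0("X", seq_len(ncol(X)))
  keep <- logical(ncol(X))
  Xs <- matrix(0, nrow(X), ncol(X), dimnames = dimnames(X))
  for (j in seq_len(ncol(X))) {
    xc <- X[, j] - sum(r * X[, j])
    ssq <- sum(r * xc^2)
    if (ssq > 1e-12 * max(1, sum(r * X[, j]^2))) {
      keep[j] <- TRUE
      Xs[, j] <- sqrt(r) * xc / sqrt(ssq)
    }
  }
  if (any(!keep)) {
    warning(sprintf("dropping constant constraint column(s): %s",
                    paste(colnames(X)[!keep], collapse = ", ")), call. = FALSE)
  }
  Xs[, keep, drop = FALSE]
}

# Variance-inflation screening on the sqrt-weighted standardized design.
# Exactly collinear columns are removed first (QR rank detection), then
# columns are dropped greedily while any VIF exceeds the threshold.
.screen_collinear <- function(Xs, vif_threshold = 20) {
  dropped <- character(0)
  if (ncol(Xs) == 0) return(list(Xs = Xs, dropped = dropped))
  qrx <- qr(Xs)
  if (qrx$rank < ncol(Xs)) {
    aliased <- colnames(Xs)[qrx$pivot[-seq_len(qrx$rank)]]
    dropped <- c(dropped, aliased)
    Xs <- Xs[, setdiff(colnames(Xs), aliased), drop = FALSE]
  }
  while (ncol(Xs) > 1) {
    R <- crossprod(Xs)  # weighted correlation matrix (columns are unit norm)
    vif <- diag(solve(R))
    if (max(vif) <= vif_threshold) break
    worst <- colnames(Xs)[which.max(vif)]
    dropped <- c(dropped, worst)
    Xs <- Xs[, setdiff(colnames(Xs), worst), drop = FALSE]
  }
  if (length(dropped) > 0) {
    warning(sprintf("collinear constraint column(s) dropped (VIF screening): %s",
                    paste(dropped, collapse = ", ")), call. = FALSE)
  }
  list(Xs = Xs, dropped = dropped)
}

# Constrained inertia (trace) of Q projected on span(Xs); the workhorse of
# the permutation loops, kept minimal.
.cca_trace <- function(Q, Xs) {
  if (ncol(Xs) == 0) return(0)
  sum(qr.fitted(qr(Xs), Q)^2)
}

.cca_first_eig <- function(Q, Xs) {
  if (ncol(Xs) == 0) return(0)
  svd(qr.fitted(qr(Xs), Q), nu = 0, nv = 0)$d[1]^2
}

#' Canonical correspondence analysis
#'
#' Fits CCA from first principles: the chi-square standardized table `Q`
#' (see [chi_square_standardize()]) is projected, by weighted least squares
#' with the row masses as weights, onto the span of the standardized
#' constraint matrix `X`; the singular value decomposition of the fitted
#' matrix yields the canonical axes, with eigenvalues equal to the squared
#' singular values. Constrained plus residual inertia equals the total
#' inertia of the table by construction.
#'
#' Scaling `"species"` (the default, ordination focused on inter-species
#' distances) scales species scores by the singular values and leaves site
#' scores as standard coordinates; scaling `"site"` does the reverse. Each
#' axis is oriented so its largest-magnitude species score is positive.
#' Collinear constraints are screened out by variance inflation (threshold
#' 20) before fitting, with a warning naming the dropped columns.
#'
#' With `n_perm > 0`, Monte-Carlo permutation tests of the first canonical
#' eigenvalue and of the trace of all canonical axes are run by permuting
#' the rows of `X` (the full-model test); `P = (1 + b) / (1 + n_perm)` where
#' `b` counts permutation statistics at or above the observed one.
#'
#' @param Y samples x bins abundance matrix (relative or raw; non-negative).
#' @param X samples x variables numeric constraint matrix or data.frame.
#' @param scaling `"species"` (inter-species focus) or `"site"`.
#' @param vif_threshold variance-inflation threshold for dropping collinear
#'   constraints.
#' @param n_perm permutations for the global significance tests (0 skips
#'   them; 499 is the conventional Monte-Carlo choice).
#' @param seed seed for the permutation tests.
#' @return an object of class `cca_result`: eigenvalues, total / constrained
#'   / residual inertia, `species_variance_explained_pct`,
#'   `species_env_explained_pct` (share of the constrained inertia shown by
#'   the first two displayed axes), site scores (`sites_lc` linear
#'   combinations, `sites_wa` weighted averages), `species` scores, `biplot`
#'   arrow scores (weighted correlation of each constraint with each axis),
#'   and, if requested, `p_first_axis` and `p_all_axes`.
#' @export
fit_cca <- function(Y, X, scaling = c("species", "site"), vif_threshold = 20,
                    n_perm = 0, seed = NULL) {
  scaling <- match.arg(scaling)
  std <- chi_square_standardize(Y)
  Q <- std$Q; r <- std$r; c <- std$c
  n <- nrow(Q); m <- ncol(Q)
  Xs <- .standardize_constraints(X, r)
  scr <- .screen_collinear(Xs, vif_threshold)
  Xs <- scr$Xs

  if (ncol(Xs) == 0) {
    res <- list(eigenvalues = numeric(0), total_inertia = std$total_inertia,
                constrained_inertia = 0, residual_inertia = std$total_inertia,
                species_variance_explained_pct = 0,
                species_env_explained_pct = NA_real_,
                sites_lc = NULL, sites_wa = NULL, species = NULL, biplot = NULL,
                scaling = scaling, dropped_constraints = scr$dropped,
                n_axes = 0L)
    class(res) <- "cca_result"
    return(res)
  }

  qrx <- qr(Xs)
  Qfit <- qr.fitted(qrx, Q)
  constrained <- sum(Qfit^2)
  residual <- sum((Q - Qfit)^2)
  sv <- svd(Qfit)
  max_axes <- min(qrx$rank, m - 1L, n - 1L)
  pos <- which(sv$d^2 > 1e-10)
  keep <- pos[pos <= max_axes]
  d <- sv$d[keep]
  u <- sv$u[, keep, drop = FALSE]
  v <- sv$v[, keep, drop = FALSE]
  eig <- d^2

  # orient each axis so the largest-magnitude species score is positive
  for (k in seq_along(keep)) {
    j <- which.max(abs(v[, k]))
    if (v[j, k] < 0) { v[, k] <- -v[, k]; u[, k] <- -u[, k] }
  }

  ax <- paste0("CCA", seq_along(keep))
  V <- v / sqrt(c)                      # species standard coordinates
  U_lc <- u / sqrt(r)                   # site (LC) standard coordinates
  U_wa <- (Q %*% v) / sqrt(r)           # site scores as weighted averages
  if (scaling == "species") {
    species <- V %*% diag(d, length(d))
    sites_lc <- U_lc
    sites_wa <- U_wa
  } else {
    species <- V
    sites_lc <- U_lc %*% diag(d, length(d))
    sites_wa <- U_wa %*% diag(d, length(d))
  }
  biplot <- crossprod(Xs, u)            # weighted correlations with the axes
  dimnames(species) <- list(colnames(Q), ax)
  dimnames(sites_lc) <- dimnames(sites_wa) <- list(rownames(Q), ax)
  dimnames(biplot) <- list(colnames(Xs), ax)

  disp <- min(2L, length(eig))
  res <- list(
    eigenvalues = stats::setNames(eig, ax),
    total_inertia = std$total_inertia,
    constrained_inertia = constrained,
    residual_inertia = residual,
    species_variance_explained_pct = 100 * constrained / std$total_inertia,
    species_env_explained_pct = if (length(eig) > 0)
      100 * sum(eig[seq_len(disp)]) / sum(eig) else NA_real_,
    sites_lc = sites_lc, sites_wa = sites_wa, species = species,
    biplot = biplot, scaling = scaling,
    dropped_constraints = scr$dropped, n_axes = length(eig)
  )
  class(res) <- "cca_result"

  if (n_perm > 0) {
    res$p_first_axis <- cca_permutation_test(Y, X, statistic = "first_axis",
                                             n_perm = n_perm, seed = seed,
                                             vif_threshold = vif_threshold)$p_value
    res$p_all_axes <- cca_permutation_test(Y, X, statistic = "trace",
                                           n_perm = n_perm, seed = seed,
                                           vif_threshold = vif_threshold)$p_value
    res$n_perm <- as.integer(n_perm)
  }
  res
}

#' @export
print.cca_result <- function(x, ...) {
  cat("Canonical correspondence analysis\n")
  cat(sprintf("  inertia: total %.4f = constrained %.4f + residual %.4f\n",
              x$total_inertia, x$constrained_inertia, x$residual_inertia))
  cat(sprintf("  species variance explained: %.1f%%\n",
              x$species_variance_explained_pct))
  if (x$n_axes > 0) {
    cat(sprintf("  canonical eigenvalues: %s\n",
                paste(sprintf("%.4f", x$eigenvalues), collapse = ", ")))
    cat(sprintf("  species-environment relation shown by first %d axes: %.1f%%\n",
                min(2L, x$n_axes), x$species_env_explained_pct))
  }
  if (!is.null(x$p_first_axis)) {
    cat(sprintf("  permutation P (first axis): %.4g; (all axes): %.4g [%d perms]\n",
                x$p_first_axis, x$p_all_axes, x$n_perm))
  }
  if (length(x$dropped_constraints) > 0) {
    cat(sprintf("  dropped collinear constraints: %s\n",
                paste(x$dropped_constraints, collapse = ", ")))
  }
  invisible(x)
}

#' Monte-Carlo permutation test for a CCA fit
#'
#' Permutes the rows of the constraint matrix `X` (unrestricted, the
#' full-model scheme) and recomputes the chosen statistic: the first
#' canonical eigenvalue or the trace (sum) of all canonical eigenvalues.
#' `P = (1 + b) / (1 + n_perm)` with `b` the number of permutation
#' statistics greater than or equal to the observed one, so P is never 0
#' and its minimum is `1 / (1 + n_perm)`.
#'
#' @param Y abundance matrix.
#' @param X constraint matrix.
#' @param statistic `"trace"` (all canonical axes) or `"first_axis"`.
#' @param n_perm number of permutations (>= 1; default 499).
#' @param seed integer seed.
#' @param vif_threshold passed to collinearity screening of the observed fit.
#' @return list with `statistic`, `observed`, `p_value`, `n_perm`.
#' @export
cca_permutation_test <- function(Y, X, statistic = c("trace", "first_axis"),
                                 n_perm = 499, seed = NULL, vif_threshold = 20) {
  statistic <- match.arg(statistic)
  .check(n_perm >= 1, "n_perm must be >= 1")
  std <- chi_square_standardize(Y)
  Q <- std$Q; r <- std$r
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("X", seq_len(ncol(X)))
  Xs <- suppressWarnings(.screen_collinear(.standardize_constraints(X, r),
                                           vif_threshold)$Xs)
  X_used <- X[, colnames(Xs), drop = FALSE]
  stat_fun <- if (statistic == "trace") .cca_trace else .cca_first_eig
  observed <- stat_fun(Q, Xs)
  n <- nrow(Q)
  exceed <- 0L
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      Xp <- X_used[sample.int(n), , drop = FALSE]
      Xps <- .standardize_constraints(Xp, r)
      if (stat_fun(Q, Xps) >= observed) exceed <- exceed + 1L
    }
  })
  list(statistic = statistic, observed = observed,
       p_value = (1 + exceed) / (1 + n_perm), n_perm = as.integer(n_perm))
}

#' Forward selection of constraints by permutation
#'
#' Greedy forward selection: at each round every excluded variable is scored
#' by the additional constrained inertia it contributes given the included
#' set, summarized as a pseudo-F statistic
#' `F = extra inertia / (residual inertia after inclusion / df_resid)` with
#' `df_resid = n - 1 - (q + 1)` for `q` already-included variables. The best
#' candidate is tested by Monte-Carlo permutation; it enters if `P < alpha`,
#' and selection stops at the first failure (or when no candidate adds
#' inertia). The first round's test permutes the candidate column outright;
#' later rounds condition on the included variables by permuting the
#' candidate's residuals after projection on them (reduced-model residual
#' permutation).
#'
#' @param Y abundance matrix.
#' @param X candidate constraint matrix (data.frame or matrix).
#' @param alpha inclusion threshold on the permutation P (default 0.05).
#' @param n_perm permutations per test (default 499).
#' @param seed integer seed.
#' @param stat ranking statistic for candidates: `"pseudo_F"` (default) or
#'   `"extra_inertia"`.
#' @return a `forward_selection` object: data.frame `trace` with one row per
#'   tested candidate (`variable`, `extra_inertia`, `pseudo_F`, `p_value`,
#'   `included`), plus `included` (character vector in inclusion order),
#'   `alpha`, `n_perm`.
#' @export
forward_select <- function(Y, X, alpha = 0.05, n_perm = 499, seed = NULL,
                           stat = c("pseudo_F", "extra_inertia")) {
  stat <- match.arg(stat)
  std <- chi_square_standardize(Y)
  Q <- std$Q; r <- std$r; n <- nrow(Q)
  total <- std$total_inertia
  Xs_all <- .standardize_constraints(X, r)
  .check(ncol(Xs_all) >= 1, "need at least one candidate variable")
  vars <- colnames(Xs_all)
  included <- character(0)
  rows <- list()
  round_seeds <- .sub_seeds(seed %||% 1L, ncol(Xs_all) + 1L)
  round_i <- 0L

  repeat {
    round_i <- round_i + 1L
    cands <- setdiff(vars, included)
    if (length(cands) == 0) break
    Zi <- Xs_all[, included, drop = FALSE]
    tr0 <- .cca_trace(Q, Zi)
    q <- length(included)
    df_resid <- n - 1L - (q + 1L)
    .check(df_resid >= 1, "no residual degrees of freedom left for testing")

    extra <- pseudo_f <- stats::setNames(numeric(length(cands)), cands)
    for (cand in cands) {
      trc <- .cca_trace(Q, Xs_all[, c(included, cand), drop = FALSE])
      extra[cand] <- trc - tr0
      pseudo_f[cand] <- (trc - tr0) / ((total - trc) / df_resid)
    }
    score <- if (stat == "pseudo_F") pseudo_f else extra
    best <- names(which.max(score))
    if (extra[best] < 1e-12) {
      rows[[length(rows) + 1L]] <- data.frame(
        round = round_i, variable = best, extra_inertia = extra[best],
        pseudo_F = 0, p_value = NA_real_, included = FALSE)
      break
    }

    # permute the best candidate's component not explained by the included set
    z <- Xs_all[, best]
    if (q > 0) {
      qz <- qr(Zi)
      e <- qr.resid(qz, z)
      fitted_part <- z - e
    } else {
      e <- z
      fitted_part <- 0 * z
    }
    obs_score <- score[best]
    exceed <- 0L
    with_seed(round_seeds[round_i], {
      for (b in seq_len(n_perm)) {
        zp <- fitted_part + e[sample.int(n)]
        trp <- .cca_trace(Q, cbind(Zi, zp))
        sp <- if (stat == "pseudo_F")
          (trp - tr0) / ((total - trp) / df_resid) else trp - tr0
        if (sp >= obs_score) exceed <- exceed + 1L
      }
    })
    p <- (1 + exceed) / (1 + n_perm)
    ok <- p < alpha
    rows[[length(rows) + 1L]] <- data.frame(
      round = round_i, variable = best, extra_inertia = unname(extra[best]),
      pseudo_F = unname(pseudo_f[best]), p_value = p, included = ok)
    if (!ok) break
    included <- c(included, best)
  }

  structure(list(trace = do.call(rbind, rows), included = included,
                 alpha = alpha, n_perm = as.integer(n_perm),
                 seed = seed),
            class = "forward_selection")
}

#' @export
print.forward_selection <- function(x, ...) {
  cat(sprintf("forward selection (alpha = %g, %d permutations)\n", x$alpha, x$n_perm))
  cat(sprintf("  included: %s\n",
              if (length(x$included)) paste(x$included, collapse = ", ") else "(none)"))
  print(x$trace, row.names = FALSE)
  invisible(x)
}

#' Write CCA outputs as JSON plus TSV score tables
#'
#' @param fit a `cca_result`.
#' @param dir output directory (created if needed).
#' @param prefix filename prefix.
#' @return invisibly, the paths written.
#' @export
write_cca_result <- function(fit, dir, prefix = "cca") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  js <- file.path(dir, paste0(prefix, ".json"))
  jsonlite::write_json(list(
    eigenvalues = as.list(fit$eigenvalues),
    total_inertia = fit$total_inertia,
    constrained_inertia = fit$constrained_inertia,
    residual_inertia = fit$residual_inertia,
    species_variance_explained_pct = fit$species_variance_explained_pct,
    species_env_explained_pct = fit$species_env_explained_pct,
    p_first_axis = fit$p_first_axis, p_all_axes = fit$p_all_axes,
    scaling = fit$scaling, dropped_constraints = fit$dropped_constraints
  ), js, auto_unbox = TRUE, digits = NA, null = "null")
  paths <- c(paths, js)
  for (tab in c("sites_lc", "sites_wa", "species", "biplot")) {
    if (is.null(fit[[tab]])) next
    p <- file.path(dir, paste0(prefix, "_", tab, ".tsv"))
    df <- data.frame(label = rownames(fit[[tab]]), fit[[tab]], check.names = FALSE)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
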