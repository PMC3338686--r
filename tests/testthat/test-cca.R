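test_that("chi-square standardization matches its defining identities", {
  # independent rows/columns (rank-one table): zero residual, zero inertia
  Y_ind <- outer(c(1, 2, 3), c(4, 1, 5))
  std <- chi_square_standardize(Y_ind)
  expect_lt(max(abs(std$Q)), 1e-12)
  expect_lt(std$total_inertia, 1e-12)

  # perfectly associated 2x2 table: inertia = chi-square / N = 1
  std2 <- chi_square_standardize(matrix(c(10, 0, 0, 10), 2, 2))
  expect_equal(std2$total_inertia, 1)

  # weighted centering: sqrt(r)-weighted column sums of Q vanish
  Y <- matrix(rexp(24), 6, 4) + 0.1
  std3 <- chi_square_standardize(Y)
  expect_lt(max(abs(colSums(sqrt(std3$r) * std3$Q))), 1e-12)
  expect_equal(std3$Q, Q_oracle(Y), tolerance = 1e-12, ignore_attr = TRUE)

  Yz <- Y; Yz[2, ] <- 0
  rownames(Yz) <- paste0("s", 1:6)
  expect_error(chi_square_standardize(Yz), "s2")
})

test_that("a constant constraint explains nothing", {
  Y <- random_abundance(8, 4, seed = 1)
  expect_warning(fit <- fit_cca(Y, matrix(1, 8, 1)), "constant")
  expect_equal(fit$constrained_inertia, 0)
  expect_equal(fit$n_axes, 0L)
  expect_equal(fit$residual_inertia, fit$total_inertia)
})

test_that("full-rank constraints recover unconstrained CA eigenvalues", {
  set.seed(7)
  for (rep in 1:20) {
    Y <- matrix(rexp(24) + 0.05, 6, 4,
                dimnames = list(paste0("s", 1:6), paste0("b", 1:4)))
    X <- cbind(stats::model.matrix(~ factor(1:6))[, -1])  # n-1 free dummies
    fit <- fit_cca(Y, X)
    expect_equal(unname(fit$eigenvalues), ca_eigen_oracle(Y), tolerance = 1e-8)
  }
})

test_that("constrained plus residual inertia equals total inertia", {
  set.seed(8)
  for (rep in 1:20) {
    Y <- matrix(rexp(24) + 0.05, 6, 4)
    X <- matrix(rnorm(12), 6, 2)
    fit <- fit_cca(Y, X)
    expect_lt(abs(fit$total_inertia - fit$constrained_inertia - fit$residual_inertia),
              1e-9)
    expect_true(all(diff(fit$eigenvalues) <= 1e-12))
    expect_true(all(fit$eigenvalues >= 0 & fit$eigenvalues < 1))
  }
})

test_that("the engine agrees with an established CCA implementation", {
  set.seed(9)
  Y <- matrix(rexp(72) + 0.05, 24, 3,
              dimnames = list(sprintf("S%02d", 1:24), c("219", "354", "491")))
  X <- matrix(rnorm(24 * 4), 24, 4, dimnames = list(NULL, paste0("v", 1:4)))
  fit <- fit_cca(Y, X)
  ref <- vegan::cca(Y ~ ., data = as.data.frame(X))
  expect_equal(unname(fit$eigenvalues), unname(ref$CCA$eig), tolerance = 1e-8)
  expect_equal(fit$total_inertia, ref$tot.chi, tolerance = 1e-10)
  expect_equal(fit$constrained_inertia, ref$CCA$tot.chi, tolerance = 1e-10)
})

test_that("fits are invariant to affine rescaling of a constraint column", {
  Y <- random_abundance(10, 4, seed = 10)
  X <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  f1 <- fit_cca(Y, X)
  X2 <- X; X2[, 1] <- 3.7 * X2[, 1] - 42
  f2 <- fit_cca(Y, X2)
  expect_equal(f1$eigenvalues, f2$eigenvalues, tolerance = 1e-10)
  expect_equal(abs(f1$species), abs(f2$species), tolerance = 1e-8)
  expect_equal(abs(f1$sites_lc), abs(f2$sites_lc), tolerance = 1e-8)
})

test_that("site scores are weighted-orthogonal across axes", {
  Y <- random_abundance(12, 5, seed = 12)
  X <- matrix(rnorm(36), 12, 3)
  fit <- fit_cca(Y, X)
  r <- chi_square_standardize(Y)$r
  G <- t(fit$sites_lc) %*% (r * fit$sites_lc)
  expect_equal(unname(G), diag(nrow(G)), tolerance = 1e-10)
})

test_that("rank-deficient constraints are dropped with a warning, not silently", {
  Y <- random_abundance(10, 4, seed = 13)
  x <- rnorm(10)
  X <- cbind(a = x, b = 2 * x + 1, c = rnorm(10))
  expect_warning(fit <- fit_cca(Y, X), "collinear")
  expect_true(length(fit$dropped_constraints) >= 1)
  expect_lte(fit$n_axes, 2)
})

test_that("the planted driver carries the strongest first-axis arrow", {
  hits <- 0
  for (seed in 1:20) {
    sc <- scenario_planted_driver(seed)
    env <- simulate_env_series(sc)
    ser <- simulate_profile_series(sc, env)
    X <- as.matrix(env[, c("DO", "temperature", "SVI", "MLSS", "SRT",
                           "effluent_NO3")])
    fit <- fit_cca(ser$matrix, X)
    if (rownames(fit$biplot)[which.max(abs(fit$biplot[, 1]))] == "DO") {
      hits <- hits + 1
    }
  }
  expect_gte(hits, 19)
})

test_that("permutation P-values respect their discrete support and the seed", {
  sc <- scenario_planted_driver(2)
  env <- simulate_env_series(sc)
  ser <- simulate_profile_series(sc, env)
  X <- as.matrix(env[, c("DO", "temperature")])
  p1 <- cca_permutation_test(ser$matrix, X, "trace", n_perm = 499, seed = 5)
  p2 <- cca_permutation_test(ser$matrix, X, "trace", n_perm = 499, seed = 5)
  expect_identical(p1$p_value, p2$p_value)
  expect_gte(p1$p_value, 1 / 500)  # minimum attainable P with 499 permutations
  expect_equal(p1$p_value, 1 / 500)  # strong planted signal reaches it

  pf <- cca_permutation_test(ser$matrix, X, "first_axis", n_perm = 99, seed = 6)
  expect_gte(pf$p_value, 1 / 100)
})

test_that("forward selection stops when nothing passes and skips duplicates", {
  # independent Y and X with an inclusion threshold below the attainable P
  Y <- random_abundance(12, 4, seed = 20)
  set.seed(21)
  X <- matrix(rnorm(36), 12, 3, dimnames = list(NULL, c("a", "b", "c")))
  fs <- forward_select(Y, X, alpha = 0.001, n_perm = 199, seed = 3)
  expect_equal(length(fs$included), 0)
  expect_equal(nrow(fs$trace), 1)
  expect_false(fs$trace$included[1])

  # a duplicate of the driver never adds inertia and is never included
  sc <- scenario_planted_driver(4)
  env <- simulate_env_series(sc)
  ser <- simulate_profile_series(sc, env)
  X2 <- cbind(DO = env$DO, DO_copy = env$DO, noise = rnorm(24))
  fs2 <- forward_select(ser$matrix, X2, n_perm = 199, seed = 4)
  expect_true("DO" %in% fs2$included)
  expect_false("DO_copy" %in% fs2$included)
  dup_rows <- fs2$trace[fs2$trace$variable == "DO_copy", ]
  if (nrow(dup_rows) > 0) expect_lt(max(dup_rows$extra_inertia), 1e-10)
})

test_that("forward selection recovers the planted driver", {
  for (seed in 1:5) {
    sc <- scenario_planted_driver(100 + seed)
    env <- simulate_env_series(sc)
    ser <- simulate_profile_series(sc, env)
    X <- as.matrix(env[, c("DO", "temperature", "SVI", "MLSS", "SRT",
                           "effluent_NO3")])
    fs <- forward_select(ser$matrix, X, n_perm = 199, seed = seed)
    expect_equal(fs$included[1], "DO")
    expect_lte(fs$trace$p_value[1], 0.01)
  }
})
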