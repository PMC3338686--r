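one_var_scenario <- function(mean, sd, rho, n = 24, seed = 1) {
  trflp_scenario(
    n_samples = n,
    env_specs = data.frame(variable = "DO", mean = mean, sd = sd, rho = rho),
    response_specs = data.frame(trf = 219, driver = "DO", optimum = mean,
                                tolerance = 1, h = 1),
    trf_lengths_bp = 219, seed = seed)
}

test_that("AR(1) covariate simulation honours degenerate and boundary cases", {
  env <- simulate_env_series(one_var_scenario(mean = 5, sd = 0, rho = 0))
  expect_equal(env$DO, rep(5, 24))
  # |rho| >= 1 is non-stationary and rejected at scenario construction
  expect_error(one_var_scenario(5, 1, rho = 1.0), "rho")
  expect_error(trflp_scenario(env_specs = data.frame(
    variable = "DO", mean = 0, sd = 1, rho = -1.2)), "rho")
  # rho = 0.99 is stationary and accepted
  expect_silent(env2 <- simulate_env_series(one_var_scenario(0, 1, 0.99)))
})

test_that("AR(1) series have the requested stationary sd and lag-1 autocorrelation", {
  env <- simulate_env_series(one_var_scenario(0, 1, 0.8, n = 5000, seed = 42))
  x <- env$DO
  expect_lt(abs(cor(x[-1], x[-length(x)]) - 0.8), 0.05)
  expect_lt(abs(sd(x) - 1), 0.1)
})

test_that("unimodal responses normalize as expected at their optima", {
  # single taxon: relative abundance identically 1
  sc1 <- one_var_scenario(5, 1, 0.3, seed = 2)
  env1 <- simulate_env_series(sc1)
  ser1 <- simulate_profile_series(sc1, env1)
  expect_equal(unname(ser1$matrix[, "219"]), rep(1, 24))

  # driver pinned at the shared optimum: unnormalized abundances are the h_k,
  # so relative abundances are h_k / sum(h)
  sc2 <- trflp_scenario(
    env_specs = data.frame(variable = "DO", mean = 2, sd = 0, rho = 0),
    response_specs = data.frame(trf = c(219, 354), driver = "DO",
                                optimum = 2, tolerance = 1, h = c(0.6, 0.2)),
    trf_lengths_bp = c(219, 354), seed = 3)
  ser2 <- simulate_profile_series(sc2, simulate_env_series(sc2))
  expect_equal(unname(ser2$matrix[1, ]), c(0.75, 0.25))

  # symmetric optima around the constant driver value: 0.5 / 0.5
  sc3 <- trflp_scenario(
    env_specs = data.frame(variable = "DO", mean = 2, sd = 0, rho = 0),
    response_specs = data.frame(trf = c(219, 354), driver = "DO",
                                optimum = c(1.5, 2.5), tolerance = 0.7, h = 0.5),
    trf_lengths_bp = c(219, 354), seed = 4)
  ser3 <- simulate_profile_series(sc3, simulate_env_series(sc3))
  expect_equal(unname(ser3$matrix), matrix(0.5, 24, 2), tolerance = 1e-12)

  # a response driver absent from the covariates is reported by name
  env_bad <- simulate_env_series(sc3)
  env_bad$DO <- NULL
  expect_error(simulate_profile_series(sc3, env_bad), "DO")
})

test_that("every simulated profile is a composition and seeds reproduce bitwise", {
  sc <- scenario_planted_driver(9)
  ser <- simulate_profile_series(sc, simulate_env_series(sc))
  expect_lt(max(abs(rowSums(ser$matrix) - 1)), 1e-12)

  again <- simulate_profile_series(sc, simulate_env_series(sc))
  expect_identical(ser, again)
  pk1 <- render_peak_tables(ser, sc)
  pk2 <- render_peak_tables(again, sc)
  expect_identical(pk1, pk2)
})

test_that("Dirichlet resampling keeps compositions but adds noise", {
  sc <- scenario_planted_driver(5)
  sc$dirichlet_conc <- 300
  env <- simulate_env_series(sc)
  noisy <- simulate_profile_series(sc, env)
  sc$dirichlet_conc <- NULL
  clean <- simulate_profile_series(sc, env)
  expect_lt(max(abs(rowSums(noisy$matrix) - 1)), 1e-12)
  dev <- max(abs(noisy$matrix - clean$matrix))
  expect_gt(dev, 0)
  expect_lt(dev, 0.25)
})

test_that("rendering emits one peak per taxon plus the requested noise peaks", {
  sc <- scenario_noise_free(6)
  ser <- simulate_profile_series(sc, simulate_env_series(sc))
  pk <- render_peak_tables(ser, sc)
  # zero jitter, zero noise: lengths are exactly the bin labels
  expect_setequal(unique(pk$fragment_length), c(219, 354, 491))
  expect_equal(unname(table(pk$sample_id)[1]), 3)

  sc2 <- scenario_planted_driver(6)
  pk2 <- render_peak_tables(simulate_profile_series(sc2, simulate_env_series(sc2)), sc2)
  counts <- table(pk2$sample_id)
  expect_true(all(counts == 3 + sc2$n_noise_peaks))
  # noise peaks (those away from every true bin) land in [50, 500],
  # more than 2 bp from the true bins, and number 3 per sample
  dist_to_bin <- vapply(pk2$fragment_length,
                        function(x) min(abs(x - c(219, 354, 491))), numeric(1))
  noise_len <- pk2$fragment_length[dist_to_bin > 2]
  expect_equal(length(noise_len), 3 * 24)
  expect_true(all(noise_len >= 50 & noise_len <= 500))
})

test_that("noise-free rendering round-trips through preprocessing", {
  sc <- scenario_noise_free(7)
  env <- simulate_env_series(sc)
  ser <- simulate_profile_series(sc, env)
  pre <- preprocess_peaks(render_peak_tables(ser, sc), env)
  expect_equal(pre$series$bins, ser$bins)
  expect_lt(max(abs(pre$series$matrix - ser$matrix)), 1e-6)
})

test_that("fixed-similarity series hit the target correlation to high precision", {
  # identical consecutive profiles at target 1
  s1 <- fixed_similarity_series(10, 1, seed = 1)
  expect_lt(max(abs(diff(s1$matrix))), 1e-12)

  s9 <- fixed_similarity_series(24, 0.90, seed = 2)
  r <- vapply(seq_len(23), function(i) cor(s9$matrix[i, ], s9$matrix[i + 1, ]),
              numeric(1))
  expect_lt(max(abs(r - 0.90)), 1e-9)
  expect_lt(max(abs(rowSums(s9$matrix) - 1)), 1e-12)
  expect_true(all(s9$matrix > 0))

  s75 <- fixed_similarity_series(24, 0.75, seed = 3)
  r75 <- vapply(seq_len(23), function(i) cor(s75$matrix[i, ], s75$matrix[i + 1, ]),
                numeric(1))
  expect_lt(max(abs(r75 - 0.75)), 1e-9)

  expect_error(fixed_similarity_series(10, -1), "infeasible")
  expect_error(fixed_similarity_series(10, 1.5), "infeasible")
})

test_that("permuting the driver column destroys the planted association", {
  sc <- scenario_planted_driver(13)
  env <- simulate_env_series(sc)
  ser <- simulate_profile_series(sc, env)
  Dc <- community_distance(ser, "bray-curtis")
  r_true <- mantel_test(Dc, variable_distance(env, "DO"), n_perm = 99, seed = 1)$r_m
  env_perm <- env
  set.seed(99)
  env_perm$DO <- sample(env_perm$DO)
  r_perm <- mantel_test(Dc, variable_distance(env_perm, "DO"),
                        n_perm = 99, seed = 1)$r_m
  expect_gt(r_true, 0.5)
  expect_lt(r_perm, r_true / 2)
})

test_that("scenario files round-trip through YAML", {
  sc <- scenario_planted_driver(3)
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    n_samples = sc$n_samples, interval_days = sc$interval_days,
    trf_lengths_bp = sc$trf_lengths_bp,
    env_specs = lapply(seq_len(nrow(sc$env_specs)),
                       function(i) as.list(sc$env_specs[i, ])),
    response_specs = lapply(seq_len(nrow(sc$response_specs)),
                            function(i) as.list(sc$response_specs[i, ])),
    n_noise_peaks = sc$n_noise_peaks, max_noise_rel = sc$max_noise_rel,
    length_jitter_sd = sc$length_jitter_sd, total_area = sc$total_area,
    seed = sc$seed), path)
  sc2 <- read_scenario(path)
  expect_identical(simulate_env_series(sc2), simulate_env_series(sc))
})
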