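test_that("peak table CSVs parse and malformed input is reported precisely", {
  path <- write_temp_csv(toy_peaks()[1:3, ])
  pk <- read_peak_table(path)
  expect_equal(nrow(pk), 3)
  expect_named(pk, c("sample_id", "time_days", "fragment_length", "area"))

  no_area <- toy_peaks(); no_area$area <- NULL
  expect_error(read_peak_table(write_temp_csv(no_area)), "area")

  neg <- toy_peaks(); neg$area[2] <- -5
  expect_error(read_peak_table(write_temp_csv(neg)), "row.*2")
})

test_that("size window keeps 50-500 bp inclusive", {
  pk <- data.frame(sample_id = "A", time_days = 0,
                   fragment_length = c(45, 219, 354, 505), area = 1)
  expect_equal(filter_size_window(pk)$fragment_length, c(219, 354))
  pk2 <- data.frame(sample_id = "A", time_days = 0,
                    fragment_length = c(50, 500), area = 1)
  expect_equal(filter_size_window(pk2)$fragment_length, c(50, 500))
  empty <- pk[0, ]
  expect_equal(nrow(filter_size_window(empty)), 0)
  expect_error(filter_size_window(pk, 500, 50), "min_bp")
})

test_that("T-RF binning is single-linkage with area-weighted integer labels", {
  two <- data.frame(sample_id = c("A", "B"), time_days = c(0, 15),
                    fragment_length = c(218.6, 219.3), area = c(100, 100))
  b <- bin_trfs(two)
  expect_equal(unique(b$fragment_length), 219)
  expect_equal(nrow(b), 2)  # one bin, present in both samples

  apart <- data.frame(sample_id = "A", time_days = 0,
                      fragment_length = c(219.0, 221.0), area = 1)
  expect_equal(length(unique(bin_trfs(apart)$fragment_length)), 2)

  chain <- data.frame(sample_id = "A", time_days = 0,
                      fragment_length = c(219.0, 219.9, 220.8), area = c(4, 1, 1))
  bc <- bin_trfs(chain)
  expect_equal(nrow(bc), 1)  # chained into one cluster, areas summed
  expect_equal(bc$area, 6)
  expect_equal(bc$fragment_length,
               round(weighted.mean(c(219.0, 219.9, 220.8), c(4, 1, 1))))

  # within-sample peaks falling in one cluster are summed
  dup <- data.frame(sample_id = "A", time_days = 0,
                    fragment_length = c(218.8, 219.2), area = c(30, 70))
  expect_equal(bin_trfs(dup)$area, 100)
})

test_that("relative abundances are per-sample area ratios", {
  prof <- relative_abundance(bin_trfs(toy_peaks()))
  expect_equal(unname(prof$A$abundances), c(0.70, 0.15, 0.15))
  single <- data.frame(sample_id = "A", time_days = 0,
                       fragment_length = 219, area = 42)
  expect_equal(unname(relative_abundance(single)$A$abundances), 1)
  equal <- data.frame(sample_id = "A", time_days = 0,
                      fragment_length = c(219, 354), area = c(5, 5))
  expect_equal(unname(relative_abundance(equal)$A$abundances), c(0.5, 0.5))
  zero <- data.frame(sample_id = "Z", time_days = 0,
                     fragment_length = c(219, 354), area = 0)
  expect_error(relative_abundance(zero), "Z")
})

test_that("noise floor removes strictly-below-2% bins and accounts for mass", {
  p <- community_profile("A", 0,
                         c("219" = 0.70, "354" = 0.15, "491" = 0.13, "137" = 0.02))
  kept <- filter_noise(p)
  expect_true("137" %in% names(kept$abundances))  # 0.02 is not < 0.02
  expect_equal(attr(kept, "removed_mass"), 0)

  q <- community_profile("A", 0,
                         c("219" = 0.70, "354" = 0.155, "491" = 0.13, "137" = 0.015))
  fq <- filter_noise(q)
  expect_equal(length(fq$abundances), 3)
  expect_equal(sum(fq$abundances), 1, tolerance = 1e-12)
  expect_equal(attr(fq, "removed_mass"), 0.015)

  raw <- filter_noise(q, renormalize = FALSE)
  expect_equal(sum(raw$abundances) + attr(raw, "removed_mass"), 1,
               tolerance = 1e-9)

  all_low <- community_profile("A", 0, setNames(rep(1 / 60, 60), 100 + seq_len(60)))
  expect_error(filter_noise(all_low), "noise floor")
})

test_that("on the synthetic preset the removed noise mass stays within 5%", {
  sc <- scenario_planted_driver(21)
  env <- simulate_env_series(sc)
  pk <- render_peak_tables(simulate_profile_series(sc, env), sc)
  pre <- preprocess_peaks(pk, env)
  expect_true(all(pre$removed_mass <= 0.05))
})

test_that("series assembly unions bins, orders by time and validates ids", {
  profs <- list(community_profile("A", 0, c("219" = 1), normalized = TRUE),
                community_profile("C", 30, c("219" = 0.4, "354" = 0.6)),
                community_profile("B", 15, c("354" = 1)))
  env <- data.frame(sample_id = c("A", "B", "C"), time_days = c(0, 15, 30),
                    DO = c(1, 2, 3))
  out <- assemble_series(profs, env)
  expect_equal(out$series$sample_ids, c("A", "B", "C"))  # resorted by time
  expect_equal(out$series$bins, c(219, 354))
  expect_equal(unname(out$series$matrix["A", ]), c(1, 0))  # explicit zero fill
  expect_equal(out$env$sample_id, c("A", "B", "C"))

  env_short <- env[env$sample_id != "B", ]
  expect_error(assemble_series(profs, env_short), "B")
})

test_that("preprocessing is idempotent and mass-conserving", {
  sc <- scenario_planted_driver(31)
  env <- simulate_env_series(sc)
  pk <- render_peak_tables(simulate_profile_series(sc, env), sc)

  once <- filter_size_window(pk)
  expect_identical(filter_size_window(once), once)
  binned <- bin_trfs(once)
  expect_identical(bin_trfs(binned), binned)

  profiles <- relative_abundance(binned)
  for (p in profiles) {
    f <- filter_noise(p, renormalize = FALSE)
    expect_equal(sum(f$abundances) + attr(f, "removed_mass"), 1, tolerance = 1e-9)
    # filtering an already-filtered profile changes nothing
    f2 <- filter_noise(filter_noise(p))
    expect_equal(f2$abundances, filter_noise(p)$abundances, tolerance = 1e-12)
  }
})

test_that("covariate tables flag missing values and reject invalid ranges", {
  env <- data.frame(sample_id = c("A", "B", "C"), time_days = c(0, 15, 30),
                    DO = c(1.8, NA, 2.0), NH3_removal_eff = c(95, 96, 97))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(env, path, row.names = FALSE)
  expect_message(out <- read_env_table(path), "missing")
  expect_true(is.na(out$DO[2]))

  env$NH3_removal_eff[1] <- 120
  write.csv(env, path, row.names = FALSE)
  expect_error(read_env_table(path), "NH3_removal_eff")

  env$NH3_removal_eff[1] <- 95
  env$DO[1] <- -1
  write.csv(env, path, row.names = FALSE)
  expect_error(read_env_table(path), "DO")
})
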