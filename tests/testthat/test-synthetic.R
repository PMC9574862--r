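test_that("generation is reproducible from the seed", {
  a <- generate_dataset(generator_config(n_compounds = 21, seed = 1))
  b <- generate_dataset(generator_config(n_compounds = 21, seed = 1))
  expect_identical(a$descriptors, b$descriptors)
  expect_identical(a$solubility, b$solubility)
  c <- generate_dataset(generator_config(n_compounds = 21, seed = 2))
  expect_false(identical(a$descriptors$brlogd, c$descriptors$brlogd))
})

test_that("the noiseless limit reproduces the generating line exactly", {
  ds <- generate_dataset(generator_config(n_compounds = 50, seed = 3,
                                          noise_sd = 0, loq_log_s = -Inf))
  f <- fit_linear(ds$descriptors$brlogd, ds$solubility$log_s)
  expect_equal(f$slope, -0.75, tolerance = 1e-12)
  expect_equal(f$intercept, -3.29, tolerance = 1e-12)
  expect_equal(f$r2, 1, tolerance = 1e-12)
})

test_that("calibrated noise lands the large-sample R2 near its target", {
  r2s <- vapply(1:20, function(s) {
    ds <- generate_dataset(generator_config(n_compounds = 2000, seed = s,
                                            loq_log_s = -Inf))
    fit_linear(ds$descriptors$brlogd, ds$solubility$log_s)$r2
  }, numeric(1))
  expect_true(all(r2s > 0.62 & r2s < 0.72))
})

test_that("slope recovery concentrates within its analytic standard error", {
  # SE(slope) = |slope| sqrt((1-R2)/R2) / sqrt(n), independent of the x-range
  n <- 200
  se <- 0.75 * sqrt(0.33 / 0.67) / sqrt(n)
  hits <- vapply(1:100, function(s) {
    ds <- generate_dataset(generator_config(n_compounds = n, seed = s,
                                            loq_log_s = -Inf))
    abs(fit_linear(ds$descriptors$brlogd, ds$solubility$log_s)$slope + 0.75) <=
      1.96 * se
  }, logical(1))
  expect_gte(mean(hits), 0.90)
  # and the estimate is unbiased within Monte-Carlo error
  slopes <- vapply(1:100, function(s) {
    ds <- generate_dataset(generator_config(n_compounds = n, seed = s,
                                            loq_log_s = -Inf))
    fit_linear(ds$descriptors$brlogd, ds$solubility$log_s)$slope
  }, numeric(1))
  expect_lt(abs(mean(slopes) + 0.75), 3 * sd(slopes) / sqrt(100))
})

test_that("descriptors stay inside the configured ranges and validate cleanly", {
  cfg <- generator_config(n_compounds = 40, seed = 6)
  ds <- generate_dataset(cfg)
  d <- ds$descriptors
  expect_true(all(d$tpsa >= 166 & d$tpsa <= 335))
  expect_true(all(d$nc >= 34 & d$nc <= 58))
  expect_true(all(d$phi >= 9 & d$phi <= 27))
  expect_true(all(d$brlogd >= 0.5 & d$brlogd <= 5.5))
  expect_identical(d$delta_log_kw_iam, d$log_kw_iam - d$clog_kw_iam)
  expect_equal(nrow(validate_dataset(ds)), 0)
})

test_that("censoring is monotone in the quantification limit", {
  fracs <- vapply(c(-7.5, -6.5, -5.5, -4.5), function(loq) {
    ds <- generate_dataset(generator_config(n_compounds = 200, seed = 11,
                                            loq_log_s = loq))
    mean(ds$solubility$censored)
  }, numeric(1))
  expect_true(all(diff(fracs) >= 0))
})

test_that("all three GSK classes are populated in most seeds at moderate n", {
  rate <- mean(vapply(1:30, function(s) {
    ds <- generate_dataset(generator_config(n_compounds = 50, seed = s))
    nlevels(droplevels(ds$solubility$gsk_class)) == 3
  }, logical(1)))
  expect_gte(rate, 0.9)
})

test_that("retention tables invert the chromatographic transforms", {
  ds <- generate_dataset(generator_config(n_compounds = 20, seed = 4))
  ret <- generate_retention_tables(ds, tau = 0)
  cd <- chromatographic_descriptors(ret)
  m <- match(cd$compound_id, ds$descriptors$id)
  expect_lt(max(abs(cd$brlogd - ds$descriptors$brlogd[m])), 1e-9)
  expect_lt(max(abs(cd$log_kw_iam - ds$descriptors$log_kw_iam[m])), 1e-9)
  expect_true(all(cd$extrapolation_r2 > 1 - 1e-12))
})

test_that("jittered retention recovery is unbiased", {
  ds <- generate_dataset(generator_config(n_compounds = 100, seed = 8))
  set.seed(80)
  ret <- generate_retention_tables(ds, tau = 0.02)
  cd <- chromatographic_descriptors(ret)
  m <- match(cd$compound_id, ds$descriptors$id)
  err <- cd$brlogd - ds$descriptors$brlogd[m]
  # BRlogD error = 3.31 * mean of 2 jitters: SE = 3.31 * 0.02 / sqrt(2*100)
  expect_lt(abs(mean(err)), 3 * 3.31 * 0.02 / sqrt(2 * 100))
})

test_that("toy ensembles respect their analytic PSA bounds", {
  degenerate <- generate_toy_ensemble(5, seed = 1, jitter = 0)
  d <- ensemble_psa_distribution(degenerate)
  expect_equal(max(d$per_conformer_psa), min(d$per_conformer_psa))
  expect_equal(d$q1, d$q3)
  single <- ensemble_psa_distribution(generate_toy_ensemble(1, seed = 2))
  expect_equal(single$median, single$upper_adjacent)
  wide <- ensemble_psa_distribution(generate_toy_ensemble(25, seed = 3,
                                                          jitter = 0.6))
  upper <- 4 * pi * (1.52^2 + 1.55^2)
  lower <- 4 * pi * max(1.52, 1.55)^2 * 0.5 # even fully fused, one hemisphere+ remains
  expect_true(all(wide$per_conformer_psa <= upper))
  expect_true(all(wide$per_conformer_psa >= lower))
})
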