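test_that("a degenerate noiseless spec reproduces the configured means exactly", {
  spec <- cohort_spec(n_male = 2, n_female = 2, stats = zero_sd_stats(),
                      size_factor_sd = 0, noise_sd = 0,
                      femur_sd = c(male = 0, female = 0))
  coh <- generate_cohort(spec, seed = 1)
  st <- spec$stats
  for (sc in coh$scans) {
    mu <- if (sc$sex == "male") st$male_mean else st$female_mean
    names(mu) <- st$muscle
    for (m in st$muscle) {
      p <- sc$profiles[[m]]
      shape <- spec$shapes[[m]]
      n_prox <- round(sc$femur_length / 5)
      pos <- p$slice_index / n_prox * 100
      # profile is exactly configured ACSAmax x shape at the sampled positions
      expect_equal(p$acsa, mu[[m]] * shape_value(shape, pos), tolerance = 1e-12)
      expect_lte(max(p$acsa), mu[[m]] + 1e-12)
    }
  }
})

test_that("a sample landing on the peak position attains the configured ACSAmax", {
  shapes <- default_muscle_shapes()
  # force VM's peak onto a sampled slice: femur 400 mm -> proximal slice 80,
  # stride 1 samples every slice, peak at 25 %FL = slice 20
  spec <- cohort_spec(n_male = 1, n_female = 0, stats = zero_sd_stats(),
                      size_factor_sd = 0, noise_sd = 0,
                      femur_sd = c(male = 0, female = 0),
                      femur_mean = c(male = 400, female = 400),
                      sampling_stride = 1L)
  coh <- generate_cohort(spec, seed = 1)
  p <- coh$scans[[1]]$profiles$VM
  expect_equal(max(p$acsa), spec$stats$male_mean[spec$stats$muscle == "VM"])
  expect_equal(p$slice_index[which.max(p$acsa)], 20L)
})

test_that("cohort generation is deterministic given the seed", {
  spec <- cohort_spec(n_male = 3, n_female = 3)
  a <- generate_cohort(spec, seed = 42)
  b <- generate_cohort(spec, seed = 42)
  expect_identical(a$table, b$table)
  c2 <- generate_cohort(spec, seed = 43)
  expect_false(identical(a$table, c2$table))

  # byte-identical serialization
  fa <- withr::local_tempfile(fileext = ".csv")
  fb <- withr::local_tempfile(fileext = ".csv")
  write_measurement_table(a$scans, fa)
  write_measurement_table(b$scans, fb)
  expect_identical(readLines(fa), readLines(fb))
})

test_that("single-sex and empty-sex cohorts are valid", {
  coh <- generate_cohort(cohort_spec(n_male = 0, n_female = 3), seed = 5)
  expect_length(coh$scans, 3L)
  expect_true(all(vapply(coh$scans, function(s) s$sex, character(1)) == "female"))
})

test_that("the shared size factor raises inter-muscle correlation monotonically", {
  set.seed(12)
  mean_cor <- function(sf) {
    spec <- cohort_spec(n_male = 120, n_female = 0, size_factor_sd = sf,
                        noise_sd = 0)
    coh <- generate_cohort(spec, seed = 2024)
    amax <- t(vapply(coh$scans,
                     function(sc) morphometry_summary(sc)$acsamax,
                     numeric(10)))
    cm <- cor(amax)
    mean(cm[upper.tri(cm)])
  }
  ladder <- vapply(c(0, 0.05, 0.1), mean_cor, numeric(1))
  expect_lt(ladder[1], ladder[2])
  expect_lt(ladder[2], ladder[3])
  expect_lt(abs(ladder[1]), 0.12)  # independent draws: correlation near zero
})

test_that("marginal ACSAmax distributions track the configured table", {
  # large single cohort: per-muscle mean within 3 SE, SD within 20%
  spec <- cohort_spec(n_male = 400, n_female = 0)
  coh <- generate_cohort(spec, seed = 7)
  amax <- t(vapply(coh$scans,
                   function(sc) morphometry_summary(sc)$acsamax,
                   numeric(10)))
  st <- spec$stats
  for (i in seq_len(nrow(st))) {
    v <- amax[, st$muscle[i]]
    se <- st$male_sd[i] / sqrt(length(v))
    expect_lt(abs(mean(v) - st$male_mean[i]), 3 * se)
    expect_lt(abs(sd(v) - st$male_sd[i]) / st$male_sd[i], 0.2)
  }
})

test_that("rasterized cohorts re-measure to the generated areas within pixelation error", {
  spec <- cohort_spec(n_male = 1, n_female = 0, noise_sd = 0,
                      femur_mean = c(male = 150, female = 150),
                      femur_sd = c(male = 0, female = 0))
  coh <- generate_cohort(spec, seed = 3)
  scan <- coh$scans[[1]]
  vol <- rasterize_scan(scan, fov_px = 600L)
  remeasured <- extract_profiles(vol, sampling_stride = 1L)
  geom <- scan$geometry
  for (m in names(scan$profiles)) {
    p <- scan$profiles[[m]]
    q <- remeasured[[m]]
    for (j in seq_along(p$slice_index)) {
      if (p$acsa[j] <= 0) next
      k <- match(p$slice_index[j], q$slice_index)
      expect_false(is.na(k))
      # pixelation bound: perimeter x pixel diagonal, for the drawn disk
      r_mm <- sqrt(p$acsa[j] * 100 / pi)
      bound_cm2 <- 2 * pi * r_mm * sqrt(geom$dx^2 + geom$dy^2) / 100
      expect_lt(abs(q$acsa[k] - p$acsa[j]), bound_cm2)
    }
  }
  # femur length survives the rasterization round trip
  expect_equal(measure_femur_length(vol), scan$femur_length)
})

test_that("recovery report is near-unbiased and covers the truth", {
  # noiseless cohort: only grid-sampling attenuation remains (< 1%)
  spec0 <- cohort_spec(n_male = 6, n_female = 6, stats = zero_sd_stats(),
                       size_factor_sd = 0, noise_sd = 0,
                       femur_sd = c(male = 0, female = 0))
  rep0 <- recovery_report(spec0, generate_cohort(spec0, seed = 1)$scans)
  expect_true(all(abs(rep0$bias) / rep0$truth < 0.01))

  # stochastic defaults: most 2-SE intervals cover the truth
  spec <- cohort_spec()
  rep1 <- recovery_report(spec, generate_cohort(spec, seed = 11)$scans)
  expect_gte(mean(rep1$covered), 0.8)
  expect_equal(nrow(rep1), 20L)
})
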