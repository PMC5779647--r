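test_that("normalization and position mapping follow their definitions", {
  expect_equal(normalize_profile(c(5, 10), 10), c(50, 100))
  expect_error(normalize_profile(c(1, 2), 0), "degenerate")

  expect_equal(map_positions(40, 0, 80), 50)
  expect_equal(map_positions(0, 0, 80), 0)
  expect_equal(map_positions(1, 0, 80), 1.25)
  expect_error(map_positions(5, 10, 10), "degenerate femur span")
  expect_warning(pos <- map_positions(c(-2, 40, 85), 0, 80), "clamped")
  expect_equal(pos, c(0, 50, 100))
})

test_that("grid interpolation is the linear two-point rule with no extrapolation", {
  # samples on grid positions: identity
  g <- interpolate_grid(c(0, 50, 100), c(10, 100, 20))
  expect_equal(g$value[g$position == 0], 10)
  expect_equal(g$value[g$position == 50], 100)
  expect_length(g$position, 21L)

  # linear midpoint
  g2 <- interpolate_grid(c(40, 50), c(20, 40))
  expect_equal(g2$value[g2$position == 45], 30)
  # absent outside the sampled extent, contiguous interior support
  expect_true(all(is.na(g2$value[g2$position < 40 | g2$position > 50])))
  expect_false(anyNA(g2$value[g2$position >= 40 & g2$position <= 50]))

  expect_error(interpolate_grid(c(10, 10), c(1, 2)), "insufficient support")
})

test_that("grid values match a brute-force interpolation oracle on random profiles", {
  set.seed(5)
  for (rep in 1:25) {
    n <- sample(3:12, 1)
    xs <- sort(runif(n, 0, 100))
    while (any(diff(xs) < 1e-6)) xs <- sort(runif(n, 0, 100))
    ys <- runif(n, 0, 100)
    g <- interpolate_grid(xs, ys)
    for (k in seq_along(g$position)) {
      expect_equal(g$value[k], interp_oracle(xs, ys, g$position[k]),
                   tolerance = 1e-12)
    }
    # linear interpolation never overshoots its bracketing samples
    inside <- !is.na(g$value)
    expect_true(all(g$value[inside] >= min(ys) - 1e-12))
    expect_true(all(g$value[inside] <= max(ys) + 1e-12))
  }
})

test_that("grid maximum is 100% up to the local-slope interpolation bound", {
  coh <- generate_cohort(cohort_spec(n_male = 5, n_female = 5), seed = 9)
  grids <- cohort_grids(coh$scans)
  for (sub in unique(grids$subject)) {
    for (m in unique(grids$muscle)) {
      sel <- grids$subject == sub & grids$muscle == m & !is.na(grids$value)
      v <- grids$value[sel]
      p <- grids$position[sel]
      expect_lte(max(v), 100 + 1e-9)
      # bound: within max local slope x one grid step of 100
      delta <- max(abs(diff(v)) / diff(p)) * 5
      expect_gte(max(v), 100 - delta - 1e-9)
    }
  }
})

test_that("refining the sampling stride perturbs the grid only slightly for smooth shapes", {
  spec3 <- cohort_spec(n_male = 1, n_female = 0, size_factor_sd = 0,
                       noise_sd = 0, femur_sd = c(male = 0, female = 0),
                       sampling_stride = 3L)
  spec1 <- spec3; spec1$sampling_stride <- 1L
  g3 <- cohort_grids(generate_cohort(spec3, seed = 2)$scans)
  g1 <- cohort_grids(generate_cohort(spec1, seed = 2)$scans)
  for (m in all_muscles()) {
    v3 <- g3$value[g3$muscle == m]; v1 <- g1$value[g1$muscle == m]
    both <- !is.na(v3) & !is.na(v1)
    # smooth analytic shapes: stride refinement moves values by a few percent
    expect_lt(max(abs(v3[both] - v1[both])), 8)
  }
})

test_that("cohort mean curves track support and degenerate SDs correctly", {
  scans <- list(toy_scan("A", "male"), toy_scan("B", "male"))
  grids <- cohort_grids(scans)
  cm <- cohort_mean_curve(grids, sex = "male", muscle = "VL")
  # two identical subjects -> SD 0 wherever supported
  expect_true(all(cm$sd[cm$n == 2] == 0))
  expect_equal(nrow(cm), 21L)

  # drop the distal end of one subject's profile: n falls at that position
  short <- toy_scan("C", "male")
  p <- short$profiles$VL
  short$profiles$VL <- muscle_profile("VL", p$slice_index[-(1:2)],
                                      p$acsa[-(1:2)])
  grids2 <- cohort_grids(list(toy_scan("A", "male"), short))
  cm2 <- cohort_mean_curve(grids2, sex = "male", muscle = "VL")
  expect_equal(cm2$n[cm2$position == 0], 1L)
  expect_true(cm2$low_support[cm2$position == 0])
  expect_equal(cm2$n[cm2$position == 50], 2L)
})

test_that("cohort mean curve stays within the SE band of the generating shape", {
  n <- 24
  spec <- cohort_spec(n_male = n, n_female = 0, noise_sd = 0.3,
                      size_factor_sd = 0.06)
  coh <- generate_cohort(spec, seed = 31)
  grids <- cohort_grids(coh$scans)
  shape <- spec$shapes$VL
  cm <- cohort_mean_curve(grids, sex = "male", muscle = "VL")
  sup <- cm$position > shape$onset + 5 & cm$position < shape$offset - 5
  truth <- 100 * shape_value(shape, cm$position[sup])
  dev <- abs(cm$mean[sup] - truth)
  se <- cm$sd[sup] / sqrt(cm$n[sup])
  # allow 4 SE plus a small grid-discretization allowance
  expect_true(all(dev <= 4 * se + 2))
})
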