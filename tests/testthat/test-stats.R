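test_that("pooled t-test matches the hand formula and is label-symmetric", {
  a <- c(1, 2, 3); b <- c(11, 12, 13)
  res <- independent_t(a, b)
  oracle <- pooled_t_oracle(a, b)
  expect_equal(res$t, oracle$t)
  expect_equal(res$df, oracle$df)
  expect_equal(res$p, oracle$p)
  expect_lt(res$p, 0.001)

  # identical groups: t = 0, p = 1 (give them nonzero variance)
  same <- c(1, 2, 3, 4)
  res0 <- independent_t(same, same)
  expect_equal(res0$t, 0)
  expect_equal(res0$p, 1)

  # exchanging group labels flips t, leaves p unchanged
  set.seed(21)
  x <- rnorm(9); y <- rnorm(12, 0.5)
  expect_equal(independent_t(x, y)$p, independent_t(y, x)$p)
  expect_equal(independent_t(x, y)$t, -independent_t(y, x)$t)

  expect_error(independent_t(c(1, 1), c(1, 1)), "undefined statistic")
  expect_error(independent_t(1, c(1, 2)), "at least 2")
})

test_that("t-test type-I error is calibrated on null simulations", {
  set.seed(1234)
  reps <- 2000
  p <- replicate(reps, {
    independent_t(rnorm(10), rnorm(10))$p
  })
  rate <- mean(p < 0.05)
  ci_half <- 2.58 * sqrt(0.05 * 0.95 / reps)
  expect_lt(abs(rate - 0.05), ci_half)
})

test_that("Cohen's d follows the (n-1)-weighted pooled formula", {
  same <- c(1, 2, 3)
  expect_equal(cohens_d(same, same)$d, 0)
  expect_error(cohens_d(c(1, 1), c(1, 1)), "zero pooled SD")

  # summary-statistic interface against the hand formula
  es <- cohens_d(mean_a = 93.6, mean_b = 70.9, sd_a = 10.3, sd_b = 12.1,
                 n_a = 32, n_b = 34)
  pooled <- sqrt((31 * 10.3^2 + 33 * 12.1^2) / 64)
  expect_equal(es$pooled_sd, pooled)
  expect_equal(es$d, 22.7 / pooled)
  expect_equal(round(es$d, 2), 2.02)

  # unit-variance groups one mean apart: d -> 1 at large n
  set.seed(8)
  x <- rnorm(20000); y <- rnorm(20000, 1)
  expect_equal(cohens_d(x, y)$d, 1, tolerance = 0.05)

  # unsigned by construction
  expect_equal(cohens_d(x, y)$d, cohens_d(y, x)$d)
})

test_that("Holm adjustment equals the hand step-down oracle", {
  expect_equal(holm_bonferroni(0.2), 0.2)
  expect_equal(holm_bonferroni(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  # all equal: smallest adjusted = m * q capped at 1
  expect_equal(holm_bonferroni(rep(0.3, 5))[1], min(5 * 0.3, 1))

  set.seed(17)
  for (i in 1:20) {
    p <- runif(sample(1:12, 1))
    adj <- holm_bonferroni(p)
    expect_equal(adj, holm_oracle(p))
    expect_true(all(adj >= p))                    # never below raw
    expect_true(all(adj <= pmin(length(p) * p, 1) + 1e-12))  # <= Bonferroni
    expect_true(all(diff(adj[order(p)]) >= -1e-12))          # monotone
  }
  expect_error(holm_bonferroni(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("two-way ANOVA detects a pure sex shift and degenerates to t^2", {
  # additive sex shift on every muscle: strong sex main effect
  set.seed(4)
  make_long <- function(shift) {
    subj <- rep(sprintf("S%02d", 1:12), each = 4)
    sex <- rep(rep(c("male", "female"), each = 6), each = 4)
    muscle <- rep(c("VM", "VI", "VL", "RF"), times = 12)
    mu <- c(VM = 24, VI = 26, VL = 29, RF = 14)[muscle]
    value <- mu + ifelse(sex == "male", shift, 0) +
      rep(rnorm(12, 0, 2), each = 4) + rnorm(48, 0, 1)
    data.frame(subject = subj, sex = sex, muscle = muscle, value = value)
  }
  d <- make_long(shift = 8)
  res <- two_way_anova(d, within = "muscle")
  eff <- res$effects
  expect_lt(eff$p[eff$effect == "sex"], 0.001)
  expect_gt(eff$p[eff$effect == "sex:muscle"], 0.01)  # no interaction built in
  expect_true(all(eff$F >= 0))

  # single within-level: F equals the pooled t squared
  d1 <- d[d$muscle == "VM", ]
  res1 <- two_way_anova(d1, within = "muscle")
  tt <- independent_t(d1$value[d1$sex == "male"], d1$value[d1$sex == "female"])
  expect_equal(res1$effects$F[1], tt$t^2, tolerance = 1e-10)
  expect_equal(res1$effects$p[1], tt$p, tolerance = 1e-10)

  # both designs available
  resb <- two_way_anova(d, within = "muscle", design = "between")
  expect_equal(sort(resb$effects$effect), sort(eff$effect))

  expect_error(two_way_anova(d[-(1:4), ][1:4, ], within = "muscle"),
               "n < 2|both sexes")
})

test_that("ANOVA interaction type-I error is near alpha under a null generator", {
  set.seed(99)
  reps <- 400
  hits <- 0L
  for (r in seq_len(reps)) {
    subj <- rep(sprintf("S%02d", 1:10), each = 3)
    sex <- rep(rep(c("male", "female"), each = 5), each = 3)
    muscle <- rep(c("VM", "VI", "VL"), times = 10)
    value <- rep(rnorm(10, 0, 1), each = 3) + rnorm(30)
    d <- data.frame(subject = subj, sex = sex, muscle = muscle, value = value)
    p <- two_way_anova(d, within = "muscle")$effects
    if (p$p[p$effect == "sex:muscle"] < 0.05) hits <- hits + 1L
  }
  rate <- hits / reps
  ci_half <- 2.58 * sqrt(0.05 * 0.95 / reps)
  expect_lt(abs(rate - 0.05), ci_half + 0.01)
})

test_that("region scan finds exactly the constructed separation band", {
  # two sexes identical except a 10-SD shift over 30-60 %FL
  set.seed(55)
  make_grids <- function(shift_band) {
    pos <- seq(0, 100, by = 5)
    rows <- list()
    for (sex in c("male", "female")) {
      for (i in 1:10) {
        val <- 50 + rnorm(length(pos), 0, 1)
        if (sex == "male" && shift_band) {
          val[pos >= 30 & pos <= 60] <- val[pos >= 30 & pos <= 60] + 10
        }
        rows[[length(rows) + 1L]] <- data.frame(
          subject = paste0(sex, i), sex = sex, muscle = "VL",
          position = pos, value = val)
      }
    }
    do.call(rbind, rows)
  }
  res <- flfl_region_scan(make_grids(TRUE), "VL")
  expect_equal(res$regions, data.frame(start = 30, end = 60))

  # identical sexes: no regions
  res0 <- flfl_region_scan(make_grids(FALSE), "VL")
  expect_equal(nrow(res0$regions), 0L)

  # alpha = 0: nothing can be significant
  resa <- flfl_region_scan(make_grids(TRUE), "VL", alpha = 0)
  expect_equal(nrow(resa$regions), 0L)
})

test_that("positions with insufficient support are skipped by the region scan", {
  pos <- seq(0, 100, by = 5)
  rows <- list()
  for (sex in c("male", "female")) {
    for (i in 1:4) {
      val <- 50 + (sex == "male") * 20 + rnorm(length(pos))
      val[pos == 0] <- NA  # absent distal end for everyone
      rows[[length(rows) + 1L]] <- data.frame(
        subject = paste0(sex, i), sex = sex, muscle = "SM",
        position = pos, value = val)
    }
  }
  res <- flfl_region_scan(do.call(rbind, rows), "SM")
  expect_false(res$positions$tested[res$positions$position == 0])
  expect_true(all(res$regions$start > 0))
})

test_that("family-wise error of the Holm region scan stays at or below alpha", {
  set.seed(77)
  reps <- 300
  fw <- 0L
  pos <- seq(0, 100, by = 5)
  for (r in seq_len(reps)) {
    rows <- list()
    for (sex in c("male", "female")) {
      for (i in 1:8) {
        rows[[length(rows) + 1L]] <- data.frame(
          subject = paste0(sex, i), sex = sex, muscle = "VL",
          position = pos, value = rnorm(length(pos), 50, 5))
      }
    }
    res <- flfl_region_scan(do.call(rbind, rows), "VL")
    if (nrow(res$regions) > 0L) fw <- fw + 1L
  }
  rate <- fw / reps
  # Holm guarantees FWER <= alpha; allow upward binomial noise only
  expect_lte(rate, 0.05 + 2.58 * sqrt(0.05 * 0.95 / reps))
})
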