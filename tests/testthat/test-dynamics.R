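constant_tc <- function(value = 1, days = 0:7, subset = "s", age = "young") {
  expand.grid(replicate = 1:2, day = days) |>
    transform(subset = subset, age_group = age, abundance = value)
}

test_that("trapezoidal AUC reproduces closed forms", {
  tc <- constant_tc(1)
  expect_equal(auc_timecourse(tc)$auc, 7)

  lin <- constant_tc(1)
  lin$abundance <- lin$day                     # 0 -> 7 over days 0..7
  expect_equal(auc_timecourse(lin)$auc, 24.5)

  # piecewise-linear curve sampled at its breakpoints: trapezoid is exact
  days <- c(0, 1, 4, 7)
  vals <- c(10, 2, 5, 9)
  pw <- data.frame(subset = "s", age_group = "young",
                   day = days, replicate = 1, abundance = vals)
  closed <- sum(diff(days) * (head(vals, -1) + vals[-1]) / 2)
  expect_equal(auc_timecourse(pw)$auc, closed, tolerance = 1e-12)

  expect_error(auc_timecourse(pw[pw$day == 0, ]), "fewer than 2")
})

test_that("AUC is linear in the abundances", {
  set.seed(61)
  base <- expand.grid(replicate = 1:3, day = c(0, 1, 4, 7))
  x <- transform(base, subset = "s", age_group = "young",
                 abundance = runif(nrow(base), 1, 5))
  y <- x
  y$abundance <- runif(nrow(base), 1, 5)
  mix <- x
  mix$abundance <- 2 * x$abundance + 3 * y$abundance
  expect_equal(auc_timecourse(mix)$auc,
               2 * auc_timecourse(x)$auc + 3 * auc_timecourse(y)$auc,
               tolerance = 1e-12)
})

test_that("recovery fraction is anchored at 100% and scales linearly", {
  tc <- rbind(constant_tc(8, age = "young"), constant_tc(20, age = "aged"))
  tc$abundance[tc$day == 1] <- tc$abundance[tc$day == 1] / 2
  rec <- recovery_fraction(tc)
  expect_equal(rec$recovery_pct[rec$day == 0], c(100, 100))
  expect_equal(rec$recovery_pct[rec$day == 1], c(50, 50))

  z <- constant_tc(0)
  expect_error(recovery_fraction(z), "zero baseline")
  expect_error(recovery_fraction(constant_tc(1, days = 1:7)), "no baseline")
})

test_that("noiseless generator output equals its closed-form mean curve", {
  sp <- timecourse_spec(noise_cv = 0, replicates = 3, seed = 3)
  tc <- make_timecourse(sp)
  m <- timecourse_mean(sp)
  expect_equal(tc$abundance,
               unname(mapply(m, tc$subset, tc$age_group, tc$day)),
               tolerance = 1e-12)
  expect_equal(tc$abundance[tc$day == 0],
               unname(sp$baseline[tc$subset[tc$day == 0]]))

  # noiseless recovery matches the generator closed form
  rec <- recovery_fraction(tc)
  expect_equal(rec$recovery_pct,
               unname(100 * mapply(m, rec$subset, rec$age_group, rec$day) /
                        sp$baseline[rec$subset]),
               tolerance = 1e-12)

  flat <- make_timecourse(timecourse_spec(
    noise_cv = 0, replicates = 2,
    depletion_depth = c(cTEC = 0, mTEC = 0, aaTEC1 = 0, aaTEC2 = 0),
    seed = 4))
  expect_equal(flat$abundance, unname(sp$baseline[flat$subset]),
               tolerance = 1e-12)
})

test_that("time-course generation is deterministic under its seed", {
  a <- make_timecourse(timecourse_spec(seed = 5))
  b <- make_timecourse(timecourse_spec(seed = 5))
  expect_identical(a, b)
  c <- make_timecourse(timecourse_spec(seed = 6))
  expect_false(identical(a, c))
})

test_that("aging index reproduces exact ratios and flags undefined series", {
  tc <- rbind(constant_tc(3, age = "young"), constant_tc(3, age = "aged"))
  idx <- aging_index(tc, n_boot = 50, seed = 1)
  expect_equal(idx$index, 1)

  tc2 <- rbind(constant_tc(3, age = "young"), constant_tc(6, age = "aged"))
  idx2 <- aging_index(tc2, n_boot = 50, seed = 1)
  expect_equal(idx2$index, 2)

  # invariance to common rescaling of both age groups
  tc3 <- tc2
  tc3$abundance <- tc3$abundance * 17
  idx3 <- aging_index(tc3, n_boot = 50, seed = 1)
  expect_equal(idx3$index, idx2$index)

  tc0 <- rbind(constant_tc(0, age = "young"), constant_tc(1, age = "aged"))
  idx0 <- aging_index(tc0, n_boot = 10, seed = 1)
  expect_true(idx0$undefined)
  expect_true(is.na(idx0$index))

  expect_error(aging_index(constant_tc(1)), "lacks one of the age groups")
})

test_that("bootstrap CIs are seeded and have plausible width", {
  sp <- timecourse_spec(noise_cv = 0.15, replicates = 8, seed = 7,
                        subsets = "cTEC",
                        baseline = c(cTEC = 1e4),
                        depletion_depth = c(cTEC = 0.8))
  tc <- make_timecourse(sp)
  i1 <- aging_index(tc, n_boot = 300, seed = 11)
  i2 <- aging_index(tc, n_boot = 300, seed = 11)
  expect_identical(i1, i2)
  expect_true(i1$ci_lo < i1$index && i1$index < i1$ci_hi)
})
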