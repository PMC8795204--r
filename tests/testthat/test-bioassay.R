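test_that("ED50 interpolation matches hand-computed crossings", {
  # linear fall from 100% at dose 0 to 0% at 1 uM crosses 50% at 0.5
  lin <- ed50_interpolate(c(0, 1), c(100, 0))
  expect_equal(lin$value, 0.5)
  expect_false(lin$censored)
  # (100, 80, 40) at (0, 0.1, 0.5): 0.1 + 30/40 * 0.4 = 0.4
  expect_equal(ed50_interpolate(c(0, 0.1, 0.5), c(100, 80, 40))$value, 0.4)
  # a flat curve never crosses: censored at the top dose
  flat <- ed50_interpolate(c(0, 0.5, 1, 2.5), rep(100, 4))
  expect_true(flat$censored)
  expect_equal(flat$value, 2.5)
  expect_error(ed50_interpolate(c(0, 1), c(0, 0)), "undefined-baseline")
})

test_that("ED50 equals the analytic inverse of piecewise-linear curves", {
  doses <- c(0, 0.05, 0.1, 0.25, 0.5, 1, 2.5)
  set.seed(17)
  for (i in 1:25) {
    # random strictly decreasing curve crossing 50%
    drops <- sort(runif(length(doses) - 1, 0.5, 10), decreasing = FALSE)
    resp <- 100 - cumsum(c(0, drops)) / sum(drops) * runif(1, 60, 95)
    est <- ed50_interpolate(doses, resp)$value
    expect_equal(stats::approx(resp, doses, xout = 50)$y, est,
                 tolerance = 1e-10)
  }
})

test_that("ED50 of a noiseless logistic lands within one grid spacing", {
  doses <- c(0, 0.05, 0.1, 0.25, 0.5, 1, 2.5)
  for (mid in c(0.12, 0.36, 0.52)) {
    curve <- simulate_dose_response_curve(mid, hill = 1.5, doses = doses)
    est <- ed50_interpolate(curve$dose_uM, curve$response)
    i <- findInterval(mid, doses)
    expect_lt(abs(est$value - mid), doses[i + 1] - doses[i])
  }
  # dense grid, hill = 1: within 1% relative error
  dense <- simulate_dose_response_curve(0.3, hill = 1,
                                        doses = seq(0, 1,
                                                    length.out = 101))
  expect_lt(abs(ed50_interpolate(dense$dose_uM, dense$response)$value -
                  0.3) / 0.3, 0.01)
  # near-step curve: midpoint within one grid spacing of the step
  steep <- simulate_dose_response_curve(0.25, hill = 50,
                                        doses = seq(0, 1, by = 0.05))
  expect_lt(abs(ed50_interpolate(steep$dose_uM, steep$response)$value -
                  0.25), 0.05 + 1e-12)
})

test_that("per-donor ED50s summarize as mean and standard error", {
  curve <- rbind(
    data.frame(dose_uM = c(0, 0.1, 0.5), donor_id = "d1",
               response = c(100, 80, 40)),
    data.frame(dose_uM = c(0, 0.1, 0.5), donor_id = "d2",
               response = c(100, 60, 20)))
  s <- ed50_by_donor(curve)
  expect_equal(s$per_donor$d1$value, 0.4)
  expect_equal(s$per_donor$d2$value, 0.2)
  expect_equal(s$mean, 0.3)
  expect_equal(s$se, stats::sd(c(0.4, 0.2)) / sqrt(2))
})

test_that("cumulative fold expansion is split-adjusted", {
  two_weeks <- data.frame(week = 1:2, counted = c(100, 1000),
                          fraction_carried = 1)
  expect_equal(cumulative_fold_expansion(two_weeks, seed0 = 10), 100)
  # carrying only half the cells does not change per-cell expansion
  half <- data.frame(week = 1:2, counted = c(100, 500),
                     fraction_carried = c(0.5, 1))
  expect_equal(cumulative_fold_expansion(half, seed0 = 10), 100)
  one <- data.frame(week = 1, counted = 50, fraction_carried = 1)
  expect_equal(cumulative_fold_expansion(one, seed0 = 50), 1)
  # invariance across random carried fractions under fixed growth
  set.seed(23)
  for (i in 1:20) {
    fr <- runif(4, 0.2, 1)
    growth <- runif(4, 2, 12)
    counted <- numeric(4)
    seeded <- 100
    for (w in 1:4) {
      counted[w] <- seeded * growth[w]
      seeded <- counted[w] * fr[w]
    }
    p <- data.frame(week = 1:4, counted = counted, fraction_carried = fr)
    expect_equal(cumulative_fold_expansion(p, seed0 = 100), prod(growth),
                 tolerance = 1e-10)
  }
  expect_error(cumulative_fold_expansion(one, seed0 = 0), "division")
})

test_that("coating density follows mass over area", {
  expect_equal(coating_density(1, 1000, 1000), 1)
  expect_equal(coating_density(2.5, 50, 32), 3.90625)
  expect_equal(coating_density(2.5, 50, 64),
               coating_density(2.5, 50, 32) / 2)
})

test_that("delta-Ct expression doubles per cycle", {
  expect_equal(delta_ct_expression(20, 20), 1)
  expect_equal(delta_ct_expression(21, 20), 0.5)
  expect_equal(delta_ct_expression(18, 20), 4)
  set.seed(2)
  ct <- runif(20, 10, 35)
  expect_equal(delta_ct_expression(ct, ct), rep(1, 20))
  expect_error(delta_ct_expression(20), "reference")
})

test_that("group summaries report medians, bands and median ratios", {
  g <- group_summary(c(1, 2, 3, 10, 20, 30),
                     rep(c("ref", "hi"), each = 3), reference = "ref")
  expect_equal(g$median_ratio[g$group == "hi"], 10)
  expect_equal(g$median_ratio[g$group == "ref"], 1)
  single <- group_summary(c(5, 7), c("a", "b"))
  expect_equal(single$median, c(5, 7))
  expect_equal(single$iqr, c(0, 0))
  expect_equal(single$mean, single$median)
  expect_error(group_summary(numeric(), character()))
})

test_that("the normality gate routes to the right test family", {
  set.seed(41)
  gauss <- c(rnorm(12), rnorm(12))
  r <- adaptive_group_test(gauss, rep(c("a", "b"), each = 12))
  expect_equal(r$test_used, "anova-tukey")
  expect_gt(min(r$pairwise$p_adjusted), 0.05)

  set.seed(42)
  skewed <- c(rlnorm(12, 0, 2), rlnorm(12, 0, 2), rlnorm(12, 3, 2))
  r2 <- adaptive_group_test(skewed, rep(c("a", "b", "c"), each = 12))
  expect_equal(r2$test_used, "kruskal-dunn")
  expect_equal(nrow(r2$pairwise), 3)
  expect_true(all(r2$pairwise$p_adjusted >= r2$pairwise$p_value - 1e-12))

  expect_warning(r3 <- adaptive_group_test(rep(c(1, 2), each = 5),
                                           rep(c("a", "b"), each = 5)),
                 "zero-variance")
  expect_equal(r3$test_used, "none")
  expect_error(adaptive_group_test(c(1, 2, 3, 4), c("a", "a", "b", "b")),
               "at least 3")
})

test_that("Dunn z statistics agree with a direct two-group rank computation", {
  set.seed(7)
  x <- c(rnorm(8), rnorm(8, 2))
  g <- rep(c("a", "b"), each = 8)
  pw <- cytokinedoe:::dunn_posthoc(x, g)
  # independent recomputation from first principles (no ties)
  r <- rank(x)
  N <- 16
  z <- (mean(r[g == "a"]) - mean(r[g == "b"])) /
    sqrt(N * (N + 1) / 12 * (1 / 8 + 1 / 8))
  expect_equal(pw$statistic, z, tolerance = 1e-12)
})
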