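test_that("Bland-Altman limits sit exactly 2 sd either side of the mean difference", {
  same <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(c(same$mean_diff, same$sd, same$loa_low, same$loa_high),
               c(0, 0, 0, 0))

  ba <- bland_altman(c(-1, 0, -2), c(0, 0, 0))
  expect_equal(ba$mean_diff, -1)
  expect_equal(ba$sd, 1)
  expect_equal(ba$loa_low, -3)
  expect_equal(ba$loa_high, 1)

  set.seed(8)
  x <- stats::rnorm(30); y <- stats::rnorm(30)
  ba2 <- bland_altman(x, y)
  expect_equal(ba2$loa_high - ba2$mean_diff, 2 * ba2$sd)
  expect_equal(ba2$mean_diff - ba2$loa_low, 2 * ba2$sd)
  expect_error(bland_altman(1, 1), "at least two")
  expect_error(bland_altman(1:3, 1:4), "lengths differ")
})

test_that("ICC(3,k) matches the hand ANOVA decomposition and its known limits", {
  ident <- cbind(c(1, 5, 9, 13), c(1, 5, 9, 13))
  expect_equal(icc_two_way_mixed_average(ident)$icc, 1.0)

  toy <- cbind(c(1, 2, 3, 4), c(1.1, 2.0, 3.2, 3.9))
  r <- icc_two_way_mixed_average(toy)
  expect_equal(r$icc, hand_icc3k(toy), tolerance = 1e-9)
  expect_lte(r$ci_low, r$icc)
  expect_gte(r$ci_high, r$icc)

  # independent pure noise: population ICC is 0
  set.seed(99)
  noise <- cbind(stats::rnorm(200), stats::rnorm(200))
  expect_lt(abs(icc_two_way_mixed_average(noise)$icc), 0.15)

  expect_error(icc_two_way_mixed_average(cbind(c(1, 1, 1), c(1, 1, 1))),
               "between-subject")
})

test_that("ICC is invariant under common location and positive scale changes", {
  set.seed(12)
  m <- matrix(stats::rnorm(40, 10, 3), ncol = 2)
  base <- icc_two_way_mixed_average(m)$icc
  expect_equal(icc_two_way_mixed_average(m + 7.3)$icc, base, tolerance = 1e-12)
  expect_equal(icc_two_way_mixed_average(m * 2.9)$icc, base, tolerance = 1e-12)
})

test_that("the Ryan-Joiner statistic is the normal-scores correlation", {
  n <- 25
  scores <- stats::qnorm((1:n - 3 / 8) / (n + 1 / 4))
  perfect <- ryan_joiner(scores)
  expect_equal(perfect$statistic, 1, tolerance = 1e-12)
  expect_false(perfect$reject)

  x <- c(1, 2, 3, 4, 5)
  sc5 <- stats::qnorm((1:5 - 3 / 8) / (5 + 1 / 4))
  hand <- sum((x - mean(x)) * (sc5 - mean(sc5))) /
    sqrt(sum((x - mean(x))^2) * sum((sc5 - mean(sc5))^2))
  expect_equal(ryan_joiner(x)$statistic, hand, tolerance = 1e-12)

  # strongly bimodal two-point sample is rejected at alpha = 0.05
  two_pt <- rep(c(0, 1), each = 10)
  expect_true(ryan_joiner(two_pt)$reject)

  # invariant under positive affine transforms
  set.seed(4)
  y <- stats::rnorm(40)
  expect_equal(ryan_joiner(3.2 * y + 11)$statistic, ryan_joiner(y)$statistic,
               tolerance = 1e-12)
  expect_error(ryan_joiner(rep(1, 10)), "constant")
  expect_error(ryan_joiner(1:3), "n >= 4")
})

test_that("gap summaries use the (n+1)p quartile convention", {
  const <- gap_summary(rep(2.5, 6))
  expect_equal(c(const$mean, const$q1, const$q3), c(2.5, 2.5, 2.5))
  expect_null(const$normality)  # constant: no normality screen

  s <- gap_summary(c(1, 2, 3, 4))
  expect_equal(s$q1, 1.25)
  expect_equal(s$q3, 3.75)
  expect_equal(gap_summary(c(3, 4, 5))$mean, 4)
  expect_error(gap_summary(numeric(0)), "no gaps")
})

test_that("Spearman correlation matches hand ranking with average ties", {
  inc <- spearman_with_ci(1:10, (1:10)^3)
  expect_equal(inc$rho, 1)

  x <- c(1, 2, 3, 4, 5); y <- c(5, 6, 7, 8, 7)
  ry <- c(1, 2, 3.5, 5, 3.5)  # average ranks for the tied 7s
  hand <- sum((x - mean(x)) * (ry - mean(ry))) /
    sqrt(sum((x - mean(x))^2) * sum((ry - mean(ry))^2))
  r <- spearman_with_ci(x, y)
  expect_equal(r$rho, hand, tolerance = 1e-12)
  expect_lte(r$ci_low, r$rho)
  expect_gte(r$ci_high, r$rho)
  expect_equal(spearman_with_ci(y, x)$rho, r$rho)

  # Fisher-z interval with se 1.03/sqrt(n-3)
  z <- atanh(r$rho)
  expect_equal(r$ci_low, tanh(z - stats::qnorm(0.975) * 1.03 / sqrt(5 - 3)),
               tolerance = 1e-12)
  expect_error(spearman_with_ci(rep(1, 6), 1:6), "tied")
})

test_that("OLS recovers exact lines and hand-computed coefficients", {
  x <- 0:9
  f <- ols_fit(x, 2 * x + 1)
  expect_equal(f$slope, 2, tolerance = 1e-12)
  expect_equal(f$intercept, 1, tolerance = 1e-12)

  g <- ols_fit(c(0, 1, 2), c(0, 1, 1))
  expect_equal(g$slope, 0.5, tolerance = 1e-12)
  expect_equal(g$intercept, 1 / 6, tolerance = 1e-12)

  # cross-check against stats::lm on a random sample
  set.seed(17)
  xr <- stats::rnorm(50); yr <- 3 - 0.7 * xr + stats::rnorm(50)
  h <- ols_fit(xr, yr)
  co <- unname(stats::coef(stats::lm(yr ~ xr)))
  expect_equal(c(h$intercept, h$slope), co, tolerance = 1e-9)

  shifted <- ols_fit(xr, yr + 4.4)
  expect_equal(shifted$slope, h$slope, tolerance = 1e-12)
  expect_equal(shifted$intercept, h$intercept + 4.4, tolerance = 1e-9)
  expect_error(ols_fit(rep(1, 5), 1:5), "zero x variance")
})

test_that("the study equation predicts mandibular body length from SN", {
  expect_equal(predict_gome_from_sn(1e-12), 22.65, tolerance = 1e-9)
  expect_equal(predict_gome_from_sn(71), 61.1746)
  expect_equal(predict_gome_from_sn(53.7, intercept = 0, slope = 1), 53.7)
  expect_error(predict_gome_from_sn(-3), "positive")
})

test_that("the agreement table assembles mean/sd/2sd/ICC per measurement", {
  set.seed(23)
  first <- data.frame(a = stats::rnorm(12, 10), b = stats::rnorm(12, -5))
  second <- first + matrix(stats::rnorm(24, 0, 0.3), ncol = 2)
  tab <- agreement_table(first, second)
  expect_identical(rownames(tab), c("mean", "sd", "2sd", "ICC"))
  expect_identical(names(tab), c("a", "b"))
  expect_equal(tab["2sd", "a"], 2 * tab["sd", "a"])
  expect_equal(tab["mean", "b"], mean(first$b - second$b))
  expect_true(all(tab["ICC", ] > 0.9))
})
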