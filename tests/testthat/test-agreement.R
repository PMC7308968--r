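test_that("two-way ANOVA decomposition matches hand computation and stats::aov", {
  an <- two_way_anova(matrix(c(1, 3, 2, 4), 2, 2))   # [[1,2],[3,4]]
  expect_equal(an$ms_rows, 4)
  expect_equal(an$ms_cols, 1)
  expect_equal(an$ms_error, 0)
  an0 <- two_way_anova(matrix(5, 3, 4))
  expect_equal(c(an0$ms_rows, an0$ms_cols, an0$ms_error), c(0, 0, 0))
  set.seed(11)
  for (i in 1:20) {
    n <- sample(4:12, 1); k <- sample(2:5, 1)
    m <- matrix(rnorm(n * k, 20, 4), n, k)
    an <- two_way_anova(m)
    # partition identity against the directly computed total SS
    expect_equal(an$ss_rows + an$ss_cols + an$ss_error, sum((m - mean(m))^2),
                 tolerance = 1e-9)
    # independent route: stats::aov mean squares
    d <- data.frame(y = as.vector(m), subj = factor(rep(1:n, k)),
                    rater = factor(rep(1:k, each = n)))
    ms <- summary(stats::aov(y ~ subj + rater, d))[[1]][["Mean Sq"]]
    expect_equal(c(an$ms_rows, an$ms_cols, an$ms_error), ms, tolerance = 1e-9)
  }
  expect_error(two_way_anova(matrix(1:2, 1, 2)), "at least 2")
})

test_that("ICC single-measures forms behave as defined on canonical matrices", {
  ident <- cbind(c(1, 5, 9, 2), c(1, 5, 9, 2))
  expect_equal(icc_single(ident, "absolute_agreement")$estimate, 1)
  expect_equal(icc_single(ident, "consistency")$estimate, 1)
  # constant offset between columns: consistency blind, absolute penalized
  shifted <- cbind(c(1, 3, 5, 7), c(2, 4, 6, 8))
  expect_equal(icc_single(shifted, "consistency")$estimate, 1)
  ra <- icc_single(shifted, "absolute_agreement")
  expect_equal(ra$estimate, (40 / 3) / (40 / 3 + 1), tolerance = 1e-12)
  expect_lt(ra$estimate, 1)
  # all-equal matrix: zero variance everywhere is flagged, not invented
  expect_true(icc_single(matrix(3, 4, 2))$degenerate)
  # large simulated matrix recovers the closed-form ICC of its generator
  set.seed(21)
  n <- 4000; ss <- 3; se <- 1
  m <- matrix(rnorm(n, 0, ss), n, 2) + matrix(rnorm(2 * n, 0, se), n, 2)
  expect_equal(icc_single(m, "absolute_agreement")$estimate,
               ss^2 / (ss^2 + se^2), tolerance = 0.02)
  r <- icc_single(m)
  expect_true(r$ci_low <= r$estimate && r$estimate <= r$ci_high)
})

test_that("ICC interpretation bands follow the printed boundaries", {
  expect_equal(interpret_icc(0.962), "excellent")
  expect_equal(interpret_icc(0.886), "good")
  expect_equal(interpret_icc(0.9), "good")
  expect_equal(interpret_icc(0.901), "excellent")
  expect_equal(interpret_icc(0.755), "good")   # unprinted gap maps to good
  expect_equal(interpret_icc(0.75), "moderate")
  expect_equal(interpret_icc(0.5), "moderate")
  expect_equal(interpret_icc(0.49), "poor")
  # total, order-preserving step function
  rs <- seq(-1, 1, by = 0.01)
  lv <- c(poor = 1, moderate = 2, good = 3, excellent = 4)
  expect_true(all(diff(lv[vapply(rs, interpret_icc, "")]) >= 0))
})

test_that("Bland-Altman bias and limits of agreement are computed from sample SD", {
  x <- c(10, 12, 9, 14)
  ba0 <- bland_altman(x, x)
  expect_equal(c(ba0$bias, ba0$loa_low, ba0$loa_high), c(0, 0, 0))
  ba <- bland_altman(c(1, 0, 1, 0), c(0, 1, 0, 1))  # differences 1,-1,1,-1
  expect_equal(ba$bias, 0)
  expect_equal(ba$sd_diff, 1.1547005, tolerance = 1e-6)
  expect_equal(ba$loa_high, 2.2632130, tolerance = 1e-6)
  expect_equal(ba$loa_high - ba$loa_low, 2 * 1.96 * ba$sd_diff)
  shift <- bland_altman(x + 2, x)
  expect_equal(c(shift$bias, shift$loa_low, shift$loa_high), c(2, 2, 2))
  expect_named(ba$points, c("mean", "difference"))
  expect_error(bland_altman(1:3, 1:4), "length mismatch")
})

test_that("limits of agreement reconstructed from a published summary round-trip", {
  sym <- loa_from_summary(0, -1, 1, 30)
  expect_equal(sym$loa_low, -sym$loa_high)
  set.seed(13)
  x <- rnorm(50, 20, 4); y <- x + rnorm(50, 1.5, 2)
  ba <- bland_altman(x, y)
  tt <- paired_t(x, y)
  rec <- loa_from_summary(tt$md, tt$ci_low, tt$ci_high, length(x))
  expect_equal(rec$loa_low, ba$loa_low, tolerance = 1e-9)
  expect_equal(rec$loa_high, ba$loa_high, tolerance = 1e-9)
  expect_error(loa_from_summary(1, 2, 1, 10), "invalid CI")
})

test_that("paired t statistics match hand computation and stats::t.test", {
  x <- c(4, 6, 1, 9)
  same <- paired_t(x, x)
  expect_equal(c(same$md, same$t_stat, same$p), c(0, 0, 1))
  pt4 <- paired_t(c(1, 2, 3, 4) + 10, rep(10, 4))  # differences 1..4
  expect_equal(pt4$md, 2.5)
  expect_equal(pt4$df, 3)
  expect_equal(pt4$t_stat, 3.8729833, tolerance = 1e-6)
  set.seed(17)
  for (i in 1:10) {
    a <- rnorm(12, 5, 2); b <- rnorm(12, 4, 2)
    mine <- paired_t(a, b)
    ref <- stats::t.test(a, b, paired = TRUE)
    expect_equal(mine$md, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(mine$t_stat, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
    expect_equal(c(mine$ci_low, mine$ci_high), as.numeric(ref$conf.int),
                 tolerance = 1e-12)
  }
  zv <- paired_t(c(3, 3, 3), c(1, 1, 1))
  expect_true(zv$zero_variance)
  expect_lt(zv$p, 1e-300)
})

test_that("paired t confidence interval attains nominal coverage", {
  set.seed(23)
  hits <- 0; N <- 300
  for (i in 1:N) {
    x <- rnorm(50, 0, 1); y <- x - 2 + rnorm(50, 0, 1.5)
    tt <- paired_t(x, y)
    hits <- hits + (tt$ci_low <= 2 && 2 <= tt$ci_high)
  }
  expect_gt(hits / N, 0.91)
  expect_lt(hits / N, 0.99)
})

test_that("Walter sample size reproduces the closed form and is monotone", {
  ws <- walter_sample_size(0.6, 0.8, k = 2, alpha = 0.05, power = 0.8)
  expect_identical(ws$n0, 39L)
  expect_identical(walter_sample_size(0.6, 0.8, attrition = 0.10)$n_inflated, 43L)
  # monotonicity in each argument
  expect_gt(walter_sample_size(0.65, 0.8)$n0, ws$n0)
  expect_lt(walter_sample_size(0.6, 0.85)$n0, ws$n0)
  expect_gt(walter_sample_size(0.6, 0.8, power = 0.9)$n0, ws$n0)
  expect_gt(walter_sample_size(0.6, 0.62)$n0, walter_sample_size(0.6, 0.7)$n0)
  expect_error(walter_sample_size(0.7, 0.7), "rho0 < rho1")
})
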