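# sample with exact first two moments
exact_sample <- function(n, m, s, seed) {
  withr::with_seed(seed, {
    z <- rnorm(n)
    m + s * (z - mean(z)) / sd(z)
  })
}

test_that("bilateral pooling equals the moments of the concatenated per-side samples", {
  left <- exact_sample(50, 115.5, 4.11, 51)
  right <- exact_sample(50, 116.8, 3.60, 52)
  pooled <- pooled_bilateral_stats(group_stats(115.5, 4.11, 50),
                                   group_stats(116.8, 3.60, 50))
  both <- c(left, right)
  expect_equal(pooled$mean, mean(both), tolerance = 1e-12)
  expect_equal(pooled$sd, sd(both), tolerance = 1e-12)
  expect_identical(pooled$n, 100L)
  expect_equal(pooled$mean, 116.15)
  expect_equal(round(pooled$sd, 2), 3.90)

  # identical sides: pooled mean is preserved; the pooled SD carries the
  # exact concatenation Bessel factor sqrt(2(n-1)/(2n-1)), as concatenating
  # two n=10 samples with equal means and SD 0.2 does
  same <- pooled_bilateral_stats(group_stats(3, 0.2, 10), group_stats(3, 0.2, 10))
  expect_equal(same$mean, 3)
  expect_equal(same$sd, 0.2 * sqrt(2 * 9 / 19), tolerance = 1e-12)
  degen <- pooled_bilateral_stats(group_stats(5, 0, 10), group_stats(5, 0, 10))
  expect_equal(degen$sd, 0)
  expect_error(pooled_bilateral_stats(group_stats(1, 1, 10), group_stats(1, 1, 12)),
               class = "hippot2_error_pooling")
})

test_that("reference ranges are mean +/- 1.96 SD and collapse when SD is zero", {
  rr <- reference_range(group_stats(115.5, 4.11, 50))
  expect_equal(rr$lower, 115.5 - 1.96 * 4.11)
  expect_equal(rr$upper, 115.5 + 1.96 * 4.11)
  flat <- reference_range(group_stats(100, 0, 10))
  expect_equal(flat$lower, 100)
  expect_equal(flat$upper, 100)
})

test_that("well-separated clusters are classified perfectly and flagged as separated", {
  withr::local_seed(61)
  df <- tibble::tibble(
    volume_cm3 = c(rnorm(20, 3, 0.1), rnorm(20, 1.5, 0.1)),
    t2_ms = c(rnorm(20, 115, 1), rnorm(20, 135, 1)),
    pathologic = rep(c(FALSE, TRUE), each = 20))
  model <- fit_hs_classifier(df)
  pred <- classify_hippocampi(model, df)
  expect_identical(pred$pathologic_pred, df$pathologic)
  expect_true(model$separated)
  expect_false(model$converged)
  expect_error(fit_hs_classifier(df[df$pathologic, ]),
               class = "hippot2_error_single_class")
})

test_that("the IRLS fit matches an independent log-likelihood maximizer on a 20-point fixture", {
  withr::local_seed(62)
  X <- cbind(volume_cm3 = c(rnorm(10, 2.8, 0.35), rnorm(10, 2.3, 0.35)),
             t2_ms = c(rnorm(10, 116, 4), rnorm(10, 124, 6)))
  df <- tibble::as_tibble(as.data.frame(X))
  df$pathologic <- rep(c(FALSE, TRUE), each = 10)
  model <- fit_hs_classifier(df)
  expect_true(model$converged)
  ref <- oracle_logistic(X, as.integer(df$pathologic))
  expect_lt(max(abs(unname(model$coefficients) - ref)), 1e-6)
})

test_that("classification probabilities behave like a logistic in the features", {
  withr::local_seed(63)
  df <- tibble::tibble(
    volume_cm3 = c(rnorm(25, 2.9, 0.3), rnorm(25, 2.2, 0.35)),
    t2_ms = c(rnorm(25, 116, 4), rnorm(25, 127, 7)),
    pathologic = rep(c(FALSE, TRUE), each = 25))
  model <- fit_hs_classifier(df)
  b <- model$coefficients
  expect_gt(b[["t2_ms"]], 0)      # higher T2, more likely pathologic
  expect_lt(b[["volume_cm3"]], 0) # lower volume, more likely pathologic

  # a point on the decision boundary has probability exactly 0.5
  v0 <- 2.5
  t0 <- -(b[["(Intercept)"]] + b[["volume_cm3"]] * v0) / b[["t2_ms"]]
  p <- classify_hippocampi(model, tibble::tibble(volume_cm3 = v0, t2_ms = t0))
  expect_equal(p$p_pathologic, 0.5, tolerance = 1e-10)

  # monotone increasing in T2 at fixed volume
  grid <- tibble::tibble(volume_cm3 = 2.5, t2_ms = seq(100, 140, by = 2))
  expect_true(all(diff(classify_hippocampi(model, grid)$p_pathologic) > 0))

  # single-feature models are supported
  expect_length(fit_hs_classifier(df, features = "t2_ms")$coefficients, 2L)
})

test_that("the pooled t-test matches the textbook formula and its invariances", {
  res <- two_sample_t(c(1, 2, 3), c(4, 5, 6))
  # pooled var = 1, se = sqrt(2/3)
  expect_equal(res$t, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_identical(res$df, 4)
  expect_equal(res$p_value, 2 * pt(-abs(res$t), 4), tolerance = 1e-12)

  same <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)

  # joint location/scale shifts leave t unchanged
  a <- c(5.1, 6.3, 4.8, 5.9)
  b <- c(7.2, 6.8, 7.9, 8.1)
  expect_equal(two_sample_t(3 * a + 10, 3 * b + 10)$t, two_sample_t(a, b)$t,
               tolerance = 1e-12)

  expect_error(two_sample_t(c(1, 1), c(1, 1)), class = "hippot2_error_degenerate_t")
})

test_that("paired agreement reports differences, limits of agreement and correlation", {
  x <- c(110, 115, 120, 125, 118)
  same <- paired_comparison(x, x)
  expect_equal(same$mean_diff, 0)
  expect_equal(same$sd_diff, 0)
  expect_equal(same$pearson_r, 1)

  off <- paired_comparison(x + 5, x)
  expect_equal(off$mean_diff, 5)
  expect_equal(off$sd_diff, 0)

  withr::local_seed(64)
  y <- x + rnorm(5, 0, 2)
  agr <- paired_comparison(x, y)
  expect_equal(agr$loa_upper - agr$loa_lower, 2 * 1.96 * agr$sd_diff)
  expect_equal(agr$mean_diff, mean(x - y))
  expect_error(paired_comparison(x, x[-1]), class = "hippot2_error_length_mismatch")
})

test_that("the sampling distribution of the difference SD concentrates near truth at n = 40", {
  withr::local_seed(65)
  x <- rnorm(40, 116, 4)
  y <- x + rnorm(40, 0, 3.59)
  agr <- paired_comparison(x, y)
  expect_lt(abs(agr$sd_diff - 3.59) / 3.59, 0.30)
})
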