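test_that("population weights follow the capped square root", {
  expect_equal(weights_from_population(10000), 100)
  expect_equal(weights_from_population(250000), 500)
  expect_equal(weights_from_population(1e6), 500)   # cap binds
  expect_error(weights_from_population(0), "positive")
  expect_error(weights_from_population(-10), "positive")
})

test_that("weighted z-scores use the population-sd convention", {
  z <- weighted_zscore(c(1, 2, 3), rep(2, 3))
  expect_equal(z, c(-1.2247, 0, 1.2247), tolerance = 1e-4)

  set.seed(11)
  x <- rnorm(50, 10, 3)
  w <- runif(50, 0.1, 5)
  z <- weighted_zscore(x, w)
  expect_equal(weighted_mean(z, w), 0, tolerance = 1e-12)
  expect_equal(weighted_sd(z, w), 1, tolerance = 1e-12)
  expect_equal(weighted_zscore(x, 2 * w), z)        # weight-scale invariance
  expect_error(weighted_zscore(rep(4, 10), w[1:10]), "constant")
})

test_that("fit_wols matches the normal-equations oracle", {
  toy <- toy_regression(n = 20, p = 2, seed = 5)
  f <- fit_wols(toy$data, "y", toy$predictors, weights = toy$w)
  o <- ols_oracle(toy$data$y, toy$data[toy$predictors], toy$w)
  expect_equal(f$coefficients$estimate, unname(o$beta), tolerance = 1e-10)
  expect_equal(f$rss_w, o$rss_w, tolerance = 1e-10)

  # exact fit: y = 2x + 1
  d <- tibble::tibble(x = 1:10, y = 2 * (1:10) + 1)
  fe <- fit_wols(d, "y", "x", weights = runif(10, 1, 3))
  expect_equal(fe$coefficients$estimate, c(1, 2), tolerance = 1e-10)
  expect_equal(fe$r_squared, 1, tolerance = 1e-12)
  expect_lt(fe$rss_w, 1e-18)
})

test_that("equal weights reduce to ordinary least squares", {
  toy <- toy_regression(n = 60, p = 3, seed = 7)
  f <- fit_wols(toy$data, "y", toy$predictors, weights = rep(2, 60))
  ref <- lm(y ~ x1 + x2 + x3, data = toy$data)
  expect_equal(f$coefficients$estimate, unname(coef(ref)), tolerance = 1e-10)
  expect_equal(f$coefficients$std_error,
               unname(summary(ref)$coefficients[, 2]), tolerance = 1e-10)
  expect_equal(f$r_squared, summary(ref)$r.squared, tolerance = 1e-10)
})

test_that("one-tailed p-values and intervals are coherent", {
  toy <- toy_regression(seed = 13)
  f <- fit_wols(toy$data, "y", toy$predictors, weights = toy$w,
                ci_level = 0.99)
  co <- f$coefficients
  neg <- co$statistic < 0
  expect_equal(co$p_one[neg], co$p_two[neg] / 2)
  expect_equal(co$p_one[!neg], 1 - co$p_two[!neg] / 2)
  expect_true(all(co$conf_low <= co$estimate & co$estimate <= co$conf_high))
  expect_true(f$r_squared >= 0 && f$r_squared <= 1)
})

test_that("standardized coefficients equal the fit on weighted z-scores", {
  toy <- toy_regression(seed = 17)
  f <- fit_wols(toy$data, "y", toy$predictors, weights = toy$w)
  zd <- toy$data
  for (col in c("y", toy$predictors)) {
    zd[[col]] <- weighted_zscore(zd[[col]], toy$w)
  }
  fz <- fit_wols(zd, "y", toy$predictors, weights = toy$w)
  expect_equal(f$coefficients$beta_z[-1], fz$coefficients$estimate[-1],
               tolerance = 1e-8)
})

test_that("rank-deficient designs raise a singular-design error", {
  toy <- toy_regression(seed = 19)
  d <- toy$data
  d$x_dup <- d$x1 * 2
  expect_error(fit_wols(d, "y", c(toy$predictors, "x_dup"), weights = toy$w),
               "singular|collinear")
})

test_that("BIC follows the weighted-RSS formula", {
  toy <- toy_regression(seed = 23)
  f <- fit_wols(toy$data, "y", toy$predictors, weights = toy$w)
  expect_equal(bic(f),
               f$n * log(f$rss_w / f$n) + (f$k + 1) * log(f$n))
  # equal RSS, one extra term -> BIC differs by exactly log(n)
  expect_equal(wols_bic(f$rss_w, f$n, f$k + 1) - wols_bic(f$rss_w, f$n, f$k),
               log(f$n))
  # halving the RSS at fixed n, k -> BIC drops by n * log(2)
  expect_equal(wols_bic(f$rss_w / 2, f$n, f$k) - wols_bic(f$rss_w, f$n, f$k),
               -f$n * log(2))
  expect_error(wols_bic(0, 100, 3), "zero")
})

test_that("effect_percent scales by the weighted mean outcome", {
  y <- c(50, 60, 70)
  w <- c(1, 2, 1)
  expect_equal(effect_percent(-7.23, y, w), 100 * -7.23 / 60)
  expect_equal(effect_percent(0, y, w), 0)
  expect_equal(effect_percent(weighted_mean(y, w), y, w), 100)
  expect_error(effect_percent(1, c(-1, 1), c(1, 1)), "zero")
})

test_that("partial slope equals the multivariate coefficient", {
  toy <- toy_regression(n = 150, p = 5, seed = 29)
  p <- partial_regression(toy$data, "y", toy$predictors, "x2",
                          weights = toy$w)
  full <- fit_wols(toy$data, "y", toy$predictors, weights = toy$w)
  expect_equal(p$slope,
               full$coefficients$estimate[full$coefficients$term == "x2"],
               tolerance = 1e-8)
  expect_gt(p$partial_r2, 0)
  expect_lt(p$partial_r2, 1)
})

test_that("a weighted-orthogonal focal predictor gives the bivariate slope", {
  set.seed(31)
  n <- 80
  w <- runif(n, 0.5, 3)
  x1 <- rnorm(n)
  # orthogonalise x2 against x1 and the intercept in the weighted inner product
  x2 <- rnorm(n)
  x2 <- x2 - weighted_mean(x2, w) -
    sum(w * (x1 - weighted_mean(x1, w)) * (x2 - weighted_mean(x2, w))) /
    sum(w * (x1 - weighted_mean(x1, w))^2) * (x1 - weighted_mean(x1, w))
  d <- tibble::tibble(x1 = x1, x2 = x2,
                      y = 1 + 0.8 * x1 - 1.1 * x2 + rnorm(n, 0, 0.5))
  p <- partial_regression(d, "y", c("x1", "x2"), "x2", weights = w)
  biv <- fit_wols(d, "y", "x2", weights = w)
  expect_equal(p$slope,
               biv$coefficients$estimate[2], tolerance = 1e-8)
})

test_that("listwise deletion drops exactly the incomplete rows", {
  toy <- toy_regression(seed = 37)
  d <- toy$data
  d$x1[c(3, 8)] <- NA
  d$y[15] <- NA
  f <- fit_wols(d, "y", toy$predictors, weights = toy$w)
  expect_equal(f$n, nrow(d) - 3)
})
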