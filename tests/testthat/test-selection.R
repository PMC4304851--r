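test_that("best_subset matches brute-force enumeration per size", {
  toy <- toy_regression(n = 100, p = 8, seed = 41, sd = 2)
  d <- toy$data
  w <- toy$w
  scan <- best_subset(d, "y", toy$predictors, forced = "x1", weights = w)

  free <- setdiff(toy$predictors, "x1")
  for (s in seq_len(length(toy$predictors))) {
    combos <- if (s == 1) list(character(0)) else
      utils::combn(free, s - 1, simplify = FALSE)
    rss <- vapply(combos, function(extra) {
      ols_oracle(d$y, d[c("x1", extra)], w)$rss_w
    }, 0)
    rec <- scan$sizes[scan$sizes$size == s, ]
    expect_equal(rec$rss_w, min(rss), tolerance = 1e-9)
    expect_setequal(rec$members[[1]],
                    c("x1", sort(combos[[which.min(rss)]])))
  }
  # every record contains the forced predictor; per-size RSS non-increasing
  expect_true(all(vapply(scan$sizes$members, function(m) "x1" %in% m, TRUE)))
  expect_true(all(diff(scan$sizes$rss_w) <= 1e-12))
  expect_equal(scan$optimal$bic, min(scan$sizes$bic))
})

test_that("lasso path is killed at lambda_max and matches WOLS at zero", {
  toy <- toy_regression(n = 150, p = 6, seed = 43)
  w <- toy$w
  X <- as.matrix(toy$data[toy$predictors])
  Xz <- apply(X, 2, weighted_zscore, w = w)
  yz <- weighted_zscore(toy$data$y, w)
  lmax <- max(abs(crossprod(Xz, w * yz) / sum(w)))

  path <- lasso_path(yz, Xz, w, c(lmax * 1.01, lmax * 0.5, 1e-4 * lmax, 0))
  expect_true(all(path[, 1] == 0))

  zd <- tibble::as_tibble(as.data.frame(Xz))
  zd$y <- yz
  ref <- fit_wols(zd, "y", toy$predictors, weights = w)
  expect_equal(unname(path[, 4]), ref$coefficients$estimate[-1],
               tolerance = 1e-5)
})

test_that("every lasso grid solution satisfies the KKT conditions", {
  toy <- toy_regression(n = 200, p = 7, seed = 47, sd = 3)
  w <- toy$w
  Xz <- apply(as.matrix(toy$data[toy$predictors]), 2, weighted_zscore, w = w)
  yz <- weighted_zscore(toy$data$y, w)
  lambda <- lambda_grid(yz, Xz, w, n_lambda = 60)
  path <- lasso_path(yz, Xz, w, lambda)
  kkt <- vapply(seq_along(lambda), function(i) {
    lasso_kkt_residual(yz, Xz, w, path[, i], lambda[i])
  }, 0)
  expect_lt(max(kkt), 1e-6)
  # continuity along a fine grid
  fine <- exp(seq(log(max(lambda)), log(max(lambda) * 0.01),
                  by = log(0.95)))
  fine_path <- lasso_path(yz, Xz, w, fine)
  expect_lt(max(abs(diff(t(fine_path)))), 0.1)
})

test_that("the weighted lasso agrees with glmnet", {
  skip_if_not_installed("glmnet")
  toy <- toy_regression(n = 150, p = 6, seed = 53, sd = 2)
  w <- toy$w
  Xz <- apply(as.matrix(toy$data[toy$predictors]), 2, weighted_zscore, w = w)
  yz <- weighted_zscore(toy$data$y, w)
  lambda <- lambda_grid(yz, Xz, w, n_lambda = 20, lambda_min_ratio = 0.01)
  path <- lasso_path(yz, Xz, w, lambda)
  # glmnet normalises weights to sum to n, making its objective identical
  g <- glmnet::glmnet(Xz, yz, weights = w * length(yz) / sum(w),
                      lambda = lambda, standardize = FALSE,
                      intercept = FALSE, thresh = 1e-14)
  expect_equal(unname(as.matrix(g$beta)), unname(path), tolerance = 1e-4)
})

test_that("cross-validated lasso is seed-deterministic and one-SE coherent", {
  sim <- simulate_counties(sim_spec(n_counties = 300, seed = 59))
  d <- filter_counties(sim$counties)$counties
  covs <- c(covariate_sets()$lung, "elevation")
  f1 <- cv_lasso(d, "lung", covs, seed = 7)
  f2 <- cv_lasso(d, "lung", covs, seed = 7)
  expect_identical(f1$coefficients, f2$coefficients)
  expect_gte(f1$lambda_1se, f1$lambda_min)
  i <- f1$index_1se
  expect_lte(f1$cvm[i], f1$cvm[f1$index_min] + f1$cvsd[f1$index_min])
  # the largest-lambda grid solution is empty
  expect_true(all(f1$path[, 1] == 0))
})

test_that("the one-SE lasso rejects pure noise and finds strong signals", {
  set.seed(61)
  n <- 250
  null_hits <- 0
  for (s in 1:20) {
    set.seed(600 + s)
    d <- tibble::as_tibble(as.data.frame(matrix(rnorm(n * 6), n,
                                                dimnames = list(NULL, paste0("x", 1:6)))))
    d$y <- rnorm(n)
    f <- cv_lasso(d, "y", paste0("x", 1:6), weights = rep(1, n),
                  seed = s, n_lambda = 60)
    null_hits <- null_hits + (f$size == 0)
  }
  expect_gte(null_hits, 17)     # ~90%+ of null runs select nothing

  signal_hits <- 0
  for (s in 1:10) {
    set.seed(700 + s)
    d <- tibble::as_tibble(as.data.frame(matrix(rnorm(n * 6), n,
                                                dimnames = list(NULL, paste0("x", 1:6)))))
    d$y <- 2 * d$x3 + rnorm(n)
    f <- cv_lasso(d, "y", paste0("x", 1:6), weights = rep(1, n),
                  seed = s, n_lambda = 60)
    b3 <- f$coefficients$beta_z[f$coefficients$term == "x3"]
    signal_hits <- signal_hits + (b3 > 0)
  }
  expect_equal(signal_hits, 10)
})

test_that("invalid grids and fold configurations are rejected", {
  toy <- toy_regression(n = 30, p = 3, seed = 67)
  w <- toy$w
  Xz <- apply(as.matrix(toy$data[toy$predictors]), 2, weighted_zscore, w = w)
  yz <- weighted_zscore(toy$data$y, w)
  expect_error(lasso_path(yz, Xz, w, c(0.1, 0.5)), "decreasing")
  expect_error(cv_lasso(toy$data[1:5, ], "y", toy$predictors,
                        weights = w[1:5], nfolds = 10), "folds")
})
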