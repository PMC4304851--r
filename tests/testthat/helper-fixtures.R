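# Shared fixtures and independent oracles used across test files.

# Small handmade county table covering the QC columns.
tiny_counties <- function() {
  tibble::tibble(
    county_id = sprintf("%05d", 1:10),
    state = c(rep("CO", 4), rep("NM", 4), "TX", "CA"),
    population = c(50000, 9999, 120000, 30000, 15000, 2e6, 45000, 80000,
                   60000, 70000),
    immigration = c(10, 12, 41, 40, 8, 15, 9, 11, 10, 12),
    native_american = c(2, 1, 3, 4, 26, 2, 5, 3, 2, 1),
    smoking = c(45, 50, 42, 48, 51, 44, 47, 49, 46, 43),
    elevation = c(1.2, 2.0, 0.3, 1.8, 1.5, 0.1, 2.2, 0.9, 0.2, 0.5),
    lung = c(55, 60, 62, 48, 50, 65, 40, 58, 66, 63)
  )
}

# Normal-equations weighted least squares, independent of the package's
# fitting route.
ols_oracle <- function(y, X, w) {
  X <- cbind(1, as.matrix(X))
  b <- solve(t(X) %*% (w * X), t(X) %*% (w * y))
  res <- y - drop(X %*% b)
  list(beta = drop(b), rss_w = sum(w * res^2), residuals = res)
}

# A small correlated design with known coefficients for regression tests.
toy_regression <- function(n = 120, p = 4, seed = 99, sd = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  X[, 2] <- 0.6 * X[, 1] + 0.8 * X[, 2]
  colnames(X) <- paste0("x", seq_len(p))
  beta <- c(2, -1.5, rep(0.5, p - 2))
  w <- runif(n, 0.5, 4)
  y <- 1 + drop(X %*% beta) + rnorm(n, 0, sd) / sqrt(w)
  d <- tibble::as_tibble(as.data.frame(X))
  d$y <- y
  list(data = d, w = w, beta = beta, predictors = colnames(X))
}
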