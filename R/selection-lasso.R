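#' Weighted lasso coefficient path by cyclic coordinate descent
#'
#' Minimises `(1 / (2 * sum(w))) * sum(w * (y - X b)^2) + lambda * sum(|b|)`
#' on weighted-standardized inputs (weighted z-scores of every column, so no
#' intercept is needed), warm-starting each grid point from the previous
#' solution. Coordinates are updated by soft-thresholding using
#' covariance updates; convergence is declared when the largest coefficient
#' change in a full cycle falls below `tol`.
#'
#' @param y Standardized outcome (weighted mean 0, variance 1).
#' @param X Matrix of standardized predictors.
#' @param w Positive weights.
#' @param lambda Strictly decreasing penalty grid.
#' @param tol Convergence tolerance on the max coefficient change.
#' @param max_iter Cycle cap per grid point.
#' @return Matrix of coefficients, one column per `lambda`.
#' @export
lasso_path <- function(y, X, w, lambda, tol = 1e-7, max_iter = 10000L) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (is.unsorted(rev(lambda), strictly = TRUE)) {
    stop("`lambda` must be strictly decreasing", call. = FALSE)
  }
  sw <- sum(w)
  G <- crossprod(X, w * X) / sw       # weighted Gram, G[j,j] = var_w = 1
  cvec <- drop(crossprod(X, w * y)) / sw
  beta <- numeric(p)
  out <- matrix(0, p, length(lambda),
                dimnames = list(colnames(X), NULL))
  for (l in seq_along(lambda)) {
    lam <- lambda[l]
    for (iter in seq_len(max_iter)) {
      delta <- 0
      for (j in seq_len(p)) {
        rho <- cvec[j] - sum(G[j, ] * beta) + G[j, j] * beta[j]
        bj <- sign(rho) * max(abs(rho) - lam, 0) / G[j, j]
        delta <- max(delta, abs(bj - beta[j]))
        beta[j] <- bj
      }
      if (delta < tol) break
    }
    out[, l] <- beta
  }
  out
}

# KKT stationarity residual of a lasso solution: for active coefficients
# |gradient| must equal lambda, for zero coefficients be at most lambda.
lasso_kkt_residual <- function(y, X, w, beta, lambda) {
  sw <- sum(w)
  r <- y - drop(as.matrix(X) %*% beta)
  g <- drop(crossprod(as.matrix(X), w * r)) / sw
  active <- beta != 0
  viol <- pmax(abs(g) - lambda, 0)
  if (any(active)) {
    viol[active] <- pmax(viol[active], abs(abs(g[active]) - lambda))
  }
  max(viol)
}

lambda_grid <- function(y, X, w, n_lambda = 100, lambda_min_ratio = 0.001) {
  lmax <- max(abs(drop(crossprod(as.matrix(X), w * y)) / sum(w)))
  grid <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                  length.out = n_lambda))
  grid[1] <- lmax   # exact, so the largest penalty kills every coefficient
  grid
}

#' Cross-validated weighted lasso with the one-standard-error rule
#'
#' Fits the weighted lasso over a 100-point log-spaced grid from the
#' smallest all-zero penalty down to 0.1% of it, choosing the penalty by
#' seeded 10-fold cross-validation: the largest `lambda` whose CV error is
#' within one standard error (across folds) of the minimum. Standardization
#' is re-estimated on each training split; held-out error is the weighted
#' mean squared error on the original outcome scale, using the held-out
#' counties' weights. The final model is refit on all data at the chosen
#' penalty; coefficients are reported standardized and back-transformed.
#'
#' @inheritParams fit_wols
#' @param nfolds Number of cross-validation folds (default 10).
#' @param seed Integer seed controlling the fold assignment.
#' @param n_lambda,lambda_min_ratio Penalty grid shape.
#' @return A `lasso_cv` object.
#' @export
cv_lasso <- function(data, outcome, covariates, weights = NULL,
                     nfolds = 10, seed = 1L, n_lambda = 100,
                     lambda_min_ratio = 0.001, weight_cap = 250000) {
  if (is.null(weights)) {
    weights <- weights_from_population(data$population, cap = weight_cap)
  }
  used <- stats::complete.cases(data[, c(outcome, covariates), drop = FALSE])
  df_cc <- data[used, , drop = FALSE]
  w <- weights[used]
  y <- df_cc[[outcome]]
  X <- as.matrix(df_cc[, covariates, drop = FALSE])
  n <- length(y)
  if (n < nfolds) stop("fewer observations than folds", call. = FALSE)

  std <- function(M, mu, sd) sweep(sweep(M, 2, mu), 2, sd, "/")
  mu_x <- apply(X, 2, weighted_mean, w = w)
  sd_x <- apply(X, 2, weighted_sd, w = w)
  mu_y <- weighted_mean(y, w); sd_y <- weighted_sd(y, w)
  Xz <- std(X, mu_x, sd_x); yz <- (y - mu_y) / sd_y
  lambda <- lambda_grid(yz, Xz, w, n_lambda, lambda_min_ratio)

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  set.seed(seed)
  fold <- sample(rep(seq_len(nfolds), length.out = n))
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  if (min(table(fold)) < 2) stop("a fold has fewer than 2 observations",
                                 call. = FALSE)

  fold_err <- matrix(NA_real_, nfolds, length(lambda))
  for (f in seq_len(nfolds)) {
    tr <- fold != f
    mu_xt <- apply(X[tr, , drop = FALSE], 2, weighted_mean, w = w[tr])
    sd_xt <- apply(X[tr, , drop = FALSE], 2, weighted_sd, w = w[tr])
    mu_yt <- weighted_mean(y[tr], w[tr]); sd_yt <- weighted_sd(y[tr], w[tr])
    path <- lasso_path((y[tr] - mu_yt) / sd_yt,
                       std(X[tr, , drop = FALSE], mu_xt, sd_xt),
                       w[tr], lambda)
    Xte <- std(X[!tr, , drop = FALSE], mu_xt, sd_xt)
    pred <- mu_yt + sd_yt * (Xte %*% path)
    err <- (y[!tr] - pred)^2
    fold_err[f, ] <- colSums(w[!tr] * err) / sum(w[!tr])
  }
  cvm <- colMeans(fold_err)
  cvsd <- apply(fold_err, 2, stats::sd) / sqrt(nfolds)
  i_min <- which.min(cvm)
  ok <- which(cvm <= cvm[i_min] + cvsd[i_min])
  i_1se <- min(ok)                       # grid is descending: largest lambda

  full_path <- lasso_path(yz, Xz, w, lambda)
  beta_z <- full_path[, i_1se]
  beta_raw <- beta_z * sd_y / sd_x
  intercept <- mu_y - sum(beta_raw * mu_x)
  fitted <- intercept + drop(X %*% beta_raw)
  rss_w <- sum(w * (y - fitted)^2)
  tss_w <- sum(w * (y - mu_y)^2)

  coefs <- tibble::tibble(
    term = covariates,
    beta_z = unname(beta_z),
    estimate = unname(beta_raw),
    beta_pct = 100 * unname(beta_raw) / mu_y
  )

  structure(list(
    outcome = outcome, covariates = covariates, n = n,
    lambda = lambda, path = full_path, cvm = cvm, cvsd = cvsd,
    lambda_min = lambda[i_min], lambda_1se = lambda[i_1se],
    index_min = i_min, index_1se = i_1se,
    coefficients = coefs, intercept = intercept,
    size = sum(beta_z != 0),
    r_squared = 1 - rss_w / tss_w,
    seed = seed, nfolds = nfolds,
    standardization = list(mu_x = mu_x, sd_x = sd_x, mu_y = mu_y, sd_y = sd_y)
  ), class = "lasso_cv")
}

#' @export
print.lasso_cv <- function(x, ...) {
  cat(sprintf(
    "<lasso_cv> %s | n = %d, folds = %d, seed = %d\n lambda_1se = %.4g -> %d nonzero, R2 = %.3f\n",
    x$outcome, x$n, x$nfolds, x$seed, x$lambda_1se, x$size, x$r_squared))
  print(dplyr::filter(x$coefficients, .data$beta_z != 0))
  invisible(x)
}
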