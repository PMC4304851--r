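#' Weighted least-squares fit with one-tailed inference
#'
#' Fits `outcome ~ covariates` by weighted least squares, minimising
#' `sum(w * (y - X b)^2)`. Inference uses the t distribution with
#' `n - k - 1` degrees of freedom; alongside the usual two-sided p-value a
#' one-tailed p-value for coefficient negativity (`P(T <= t)`) is reported,
#' matching the directional hypothesis that incidence falls with the
#' exposure. Each coefficient is reported on three scales: raw (`estimate`),
#' standardized (`beta_z`, the slope among weighted z-scores), and as a
#' percentage of the weighted mean outcome (`beta_pct`).
#'
#' Rows with a missing value in any used column are dropped (listwise
#' deletion). Weights default to [weights_from_population()] of the
#' `population` column.
#'
#' @param data Data frame of counties.
#' @param outcome Name of the outcome column.
#' @param covariates Character vector of predictor columns.
#' @param weights Optional numeric vector of weights (one per row of
#'   `data`); by default computed from `population` with `weight_cap`.
#' @param ci_level Confidence level for coefficient intervals (default 0.99).
#' @param weight_cap Population cap used when deriving default weights.
#' @return A `wols_fit` object; see [tidy.wols_fit()] and
#'   [glance.wols_fit()].
#' @export
fit_wols <- function(data, outcome, covariates, weights = NULL,
                     ci_level = 0.99, weight_cap = 250000) {
  stopifnot(is.data.frame(data), length(outcome) == 1)
  missing_cols <- setdiff(c(outcome, covariates), names(data))
  if (length(missing_cols) > 0) {
    stop("column(s) not in data: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(weights)) {
    weights <- weights_from_population(data$population, cap = weight_cap)
  }
  stopifnot(length(weights) == nrow(data))
  used <- stats::complete.cases(data[, c(outcome, covariates), drop = FALSE])
  df_cc <- data[used, , drop = FALSE]
  w <- weights[used]
  y <- df_cc[[outcome]]
  X <- cbind(`(Intercept)` = 1,
             as.matrix(df_cc[, covariates, drop = FALSE]))
  n <- nrow(X)
  k <- length(covariates)
  if (n <= k + 1) stop("not enough complete cases (n <= k + 1)", call. = FALSE)

  qr_x <- qr(X * sqrt(w))
  if (qr_x$rank < ncol(X)) {
    dropped <- colnames(X)[qr_x$pivot[seq.int(qr_x$rank + 1, ncol(X))]]
    stop("singular design; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  fit <- stats::lm.wfit(X, y, w)
  beta <- fit$coefficients
  res <- y - drop(X %*% beta)
  rss_w <- sum(w * res^2)
  mu_y <- weighted_mean(y, w)
  tss_w <- sum(w * (y - mu_y)^2)
  dof <- n - k - 1
  sigma2 <- rss_w / dof
  xtwx_inv <- chol2inv(chol(crossprod(X, w * X)))
  se <- sqrt(sigma2 * diag(xtwx_inv))
  tval <- beta / se
  p_two <- 2 * stats::pt(-abs(tval), dof)
  p_one <- stats::pt(tval, dof)             # negativity
  tcrit <- stats::qt(1 - (1 - ci_level) / 2, dof)

  sd_y <- weighted_sd(y, w)
  sd_x <- vapply(covariates, function(v) weighted_sd(df_cc[[v]], w), 0)
  beta_z <- c(NA_real_, beta[-1] * sd_x / sd_y)
  beta_pct <- c(NA_real_, 100 * beta[-1] / mu_y)

  coefs <- tibble::tibble(
    term = colnames(X),
    estimate = unname(beta),
    std_error = unname(se),
    statistic = unname(tval),
    p_two = unname(p_two),
    p_one = unname(p_one),
    conf_low = unname(beta - tcrit * se),
    conf_high = unname(beta + tcrit * se),
    beta_z = unname(beta_z),
    beta_z_low = unname(beta_z - tcrit * se * c(NA, sd_x) / sd_y),
    beta_z_high = unname(beta_z + tcrit * se * c(NA, sd_x) / sd_y),
    beta_pct = unname(beta_pct)
  )

  structure(list(
    coefficients = coefs,
    outcome = outcome, covariates = covariates,
    n = n, k = k, df = dof,
    rss_w = rss_w, tss_w = tss_w,
    r_squared = 1 - rss_w / tss_w,
    bic = wols_bic(rss_w, n, k),
    ci_level = ci_level,
    residuals = res, fitted = drop(X %*% beta), weights = w,
    weighted_mean_y = mu_y, weighted_sd_y = sd_y, weighted_sd_x = sd_x,
    data = df_cc
  ), class = "wols_fit")
}

wols_bic <- function(rss_w, n, k) {
  if (rss_w <= 0) stop("BIC undefined: weighted RSS is zero", call. = FALSE)
  n * log(rss_w / n) + (k + 1) * log(n)
}

#' Bayesian Information Criterion of a weighted fit
#'
#' `BIC = n * log(RSS_w / n) + (k + 1) * log(n)`, with additive constants
#' omitted: only BIC differences are ever consumed (model selection and
#' Bayes factors), so constants cancel.
#'
#' @param fit A `wols_fit`.
#' @return A single number.
#' @export
bic <- function(fit) {
  stopifnot(inherits(fit, "wols_fit"))
  wols_bic(fit$rss_w, fit$n, fit$k)
}

#' Coefficient as a percentage of the weighted mean outcome
#'
#' @param beta Raw coefficient (outcome units per predictor unit).
#' @param y Outcome vector.
#' @param w Weights.
#' @return `100 * beta / weighted_mean(y, w)`.
#' @export
effect_percent <- function(beta, y, w) {
  mu <- weighted_mean(y, w)
  if (mu == 0) stop("weighted mean outcome is zero", call. = FALSE)
  100 * beta / mu
}

#' Partial regression for a focal predictor
#'
#' Computes the two residual vectors of a partial regression plot — the
#' focal predictor regressed on the remaining covariates (x-residuals) and
#' the outcome regressed on the covariates without the focal predictor
#' (y-residuals) — together with the weighted simple-regression slope of
#' y-residuals on x-residuals. By the Frisch–Waugh–Lovell theorem this
#' slope equals the focal coefficient in the full multivariate fit. The
#' partial R-squared is `1 - RSS(full) / RSS(without focal)`; the bivariate
#' R-squared of the outcome on the focal predictor alone is reported for
#' comparison.
#'
#' @inheritParams fit_wols
#' @param focus Name of the focal predictor (must be in `covariates`).
#' @return A `partial_fit` object.
#' @export
partial_regression <- function(data, outcome, covariates, focus,
                               weights = NULL, ci_level = 0.99,
                               weight_cap = 250000) {
  if (!focus %in% covariates) stop("`focus` must be one of `covariates`",
                                   call. = FALSE)
  if (is.null(weights)) {
    weights <- weights_from_population(data$population, cap = weight_cap)
  }
  used <- stats::complete.cases(data[, c(outcome, covariates), drop = FALSE])
  df_cc <- data[used, , drop = FALSE]
  w <- weights[used]
  others <- setdiff(covariates, focus)

  full <- fit_wols(df_cc, outcome, covariates, weights = w,
                   ci_level = ci_level)
  reduced <- fit_wols(df_cc, outcome, others, weights = w,
                      ci_level = ci_level)
  x_on_rest <- fit_wols(df_cc, focus, others, weights = w,
                        ci_level = ci_level)
  x_resid <- x_on_rest$residuals
  y_resid <- reduced$residuals
  slope <- sum(w * x_resid * y_resid) / sum(w * x_resid^2)
  bivar <- fit_wols(df_cc, outcome, focus, weights = w, ci_level = ci_level)

  structure(list(
    focus = focus, outcome = outcome,
    x_resid = x_resid, y_resid = y_resid, weights = w,
    slope = slope,
    partial_r2 = 1 - full$rss_w / reduced$rss_w,
    bivariate_r2 = bivar$r_squared,
    full_fit = full, n = full$n, ci_level = ci_level
  ), class = "partial_fit")
}

#' @export
print.wols_fit <- function(x, ...) {
  cat(sprintf("<wols_fit> %s ~ %d covariates | n = %d, R2 = %.3f, BIC = %.1f\n",
              x$outcome, x$k, x$n, x$r_squared, x$bic))
  print(x$coefficients, n = Inf)
  invisible(x)
}

#' @export
print.partial_fit <- function(x, ...) {
  cat(sprintf(
    "<partial_fit> %s | slope %.4f, partial R2 %.3f, bivariate R2 %.3f (n = %d)\n",
    x$focus, x$slope, x$partial_r2, x$bivariate_r2, x$n))
  invisible(x)
}
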