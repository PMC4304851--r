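#' Regression weights from county population
#'
#' Counties are weighted by the square root of their population, capped at a
#' maximum population beyond which measurement uncertainty in county-level
#' rates is assumed to have levelled off. The cap prevents a handful of very
#' large counties from dominating the fit while the square root still
#' downweights small, noisy counties.
#'
#' @param population Numeric vector of county populations (persons, > 0).
#' @param cap Population at which the weight stops growing (default 250,000).
#' @return Numeric vector of weights, `sqrt(pmin(population, cap))`.
#' @examples
#' weights_from_population(c(10000, 250000, 1e6))
#' @export
weights_from_population <- function(population, cap = 250000) {
  if (!is.numeric(population) || anyNA(population)) {
    stop("`population` must be numeric with no missing values", call. = FALSE)
  }
  if (any(population <= 0)) {
    stop("`population` must be strictly positive", call. = FALSE)
  }
  sqrt(pmin(population, cap))
}

#' Weighted mean and standard deviation
#'
#' The weighted sd uses the population convention (denominator `sum(w)`),
#' so `weighted_zscore()` output has weighted variance exactly 1.
#'
#' @param x Numeric vector.
#' @param w Positive weights, same length as `x`.
#' @return A single number.
#' @export
weighted_mean <- function(x, w) {
  stopifnot(length(x) == length(w))
  sum(w * x) / sum(w)
}

#' @rdname weighted_mean
#' @export
weighted_sd <- function(x, w) {
  mu <- weighted_mean(x, w)
  sqrt(sum(w * (x - mu)^2) / sum(w))
}

#' Weighted z-scores
#'
#' Centres and scales `x` by its weighted mean and weighted (population
#' convention) standard deviation. Rescaling all weights by a common factor
#' leaves the result unchanged.
#'
#' @inheritParams weighted_mean
#' @return Numeric vector with weighted mean 0 and weighted variance 1.
#' @export
weighted_zscore <- function(x, w) {
  sdv <- weighted_sd(x, w)
  if (!is.finite(sdv) || sdv <= 0) {
    stop("cannot z-score a constant (zero weighted variance) vector",
         call. = FALSE)
  }
  (x - weighted_mean(x, w)) / sdv
}

#' Weighted Pearson (or Spearman) correlation matrix
#'
#' @param data Data frame of numeric columns.
#' @param w Weights, one per row.
#' @param method `"pearson"` (weighted product-moment on pairwise complete
#'   cases) or `"spearman"` (weighted Pearson on ranks).
#' @return Symmetric correlation matrix.
#' @export
weighted_cor <- function(data, w, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  x <- as.matrix(data)
  p <- ncol(x)
  out <- matrix(NA_real_, p, p, dimnames = list(colnames(x), colnames(x)))
  for (i in seq_len(p)) {
    for (j in i:p) {
      ok <- stats::complete.cases(x[, i], x[, j])
      xi <- x[ok, i]; xj <- x[ok, j]; wk <- w[ok]
      if (method == "spearman") {
        xi <- rank(xi); xj <- rank(xj)
      }
      num <- sum(wk * (xi - weighted_mean(xi, wk)) * (xj - weighted_mean(xj, wk)))
      den <- sqrt(sum(wk * (xi - weighted_mean(xi, wk))^2) *
                    sum(wk * (xj - weighted_mean(xj, wk))^2))
      out[i, j] <- out[j, i] <- num / den
    }
  }
  out
}
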