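#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy and glance methods for fitted objects
#'
#' `tidy()` returns one row per term (or per-size record, stratum, or
#' penalty choice); `glance()` returns a one-row model summary.
#'
#' @param x A fitted object from this package.
#' @param ... Unused.
#' @return A tibble.
#' @name elevox-tidiers
NULL

#' @rdname elevox-tidiers
#' @method tidy wols_fit
#' @export
tidy.wols_fit <- function(x, ...) x$coefficients

#' @rdname elevox-tidiers
#' @method glance wols_fit
#' @export
glance.wols_fit <- function(x, ...) {
  tibble::tibble(n = x$n, k = x$k, r_squared = x$r_squared,
                 rss_w = x$rss_w, bic = x$bic,
                 weighted_mean_y = x$weighted_mean_y,
                 weighted_sd_y = x$weighted_sd_y)
}

#' @rdname elevox-tidiers
#' @method tidy subset_scan
#' @export
tidy.subset_scan <- function(x, ...) {
  dplyr::mutate(x$sizes,
                members = vapply(.data$members, paste, "", collapse = "+"),
                optimal = .data$size == x$optimal$size)
}

#' @rdname elevox-tidiers
#' @method glance subset_scan
#' @export
glance.subset_scan <- function(x, ...) {
  tibble::tibble(outcome = x$outcome, n = x$n,
                 size = x$optimal$size, bic = x$optimal$bic,
                 r_squared = x$fit$r_squared,
                 members = paste(x$optimal$members[[1]], collapse = "+"))
}

#' @rdname elevox-tidiers
#' @method tidy lasso_cv
#' @export
tidy.lasso_cv <- function(x, ...) x$coefficients

#' @rdname elevox-tidiers
#' @method glance lasso_cv
#' @export
glance.lasso_cv <- function(x, ...) {
  tibble::tibble(outcome = x$outcome, n = x$n, size = x$size,
                 r_squared = x$r_squared, lambda_min = x$lambda_min,
                 lambda_1se = x$lambda_1se, nfolds = x$nfolds,
                 seed = x$seed)
}

#' @rdname elevox-tidiers
#' @method tidy meta_result
#' @export
tidy.meta_result <- function(x, ...) x$strata

#' @rdname elevox-tidiers
#' @method glance meta_result
#' @export
glance.meta_result <- function(x, ...) {
  tibble::tibble(pooled = x$pooled, se = x$pooled_se,
                 conf_low = x$conf_low, conf_high = x$conf_high,
                 q = x$q, df = x$df, p_q = x$p_q,
                 i2 = x$i2, i2_low = x$i2_conf[1], i2_high = x$i2_conf[2])
}

#' @rdname elevox-tidiers
#' @method tidy partial_fit
#' @export
tidy.partial_fit <- function(x, ...) {
  tibble::tibble(x_resid = x$x_resid, y_resid = x$y_resid,
                 weight = x$weights)
}

#' @rdname elevox-tidiers
#' @method glance partial_fit
#' @export
glance.partial_fit <- function(x, ...) {
  tibble::tibble(focus = x$focus, slope = x$slope,
                 partial_r2 = x$partial_r2,
                 bivariate_r2 = x$bivariate_r2, n = x$n)
}

#' @rdname elevox-tidiers
#' @method tidy filter_report
#' @export
tidy.filter_report <- function(x, ...) x$exclusions
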