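#' Quality-control filtering of counties
#'
#' Retains counties that (in fixed rule order, first violated rule wins):
#' belong to the configured state allow-list, have population at or above
#' the minimum, have a five-year immigration rate not exceeding the
#' immigration cap, and Native American composition not exceeding the
#' composition cap. The immigration and composition rules are strict
#' (`>`): a county exactly at a cap is retained. Filtering is idempotent.
#'
#' @param data County tibble with `state`, `population`, `immigration`,
#'   and `native_american` columns.
#' @param config An `analysis_config`; thresholds are read from
#'   `config$qc`.
#' @return A list with `counties` (the retained tibble) and `report`
#'   (a `filter_report`: counts, per-county exclusions, thresholds).
#' @export
filter_counties <- function(data, config = default_config()) {
  qc <- config$qc
  need <- c("state", "population", "immigration", "native_american")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0) {
    stop("required column(s) absent: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  rule <- rep(NA_character_, nrow(data))
  rule[is.na(rule) & !data$state %in% qc$states] <- "state"
  rule[is.na(rule) & data$population < qc$min_population] <- "population"
  rule[is.na(rule) & !is.na(data$immigration) &
         data$immigration > qc$max_immigration] <- "immigration"
  rule[is.na(rule) & !is.na(data$native_american) &
         data$native_american > qc$max_native_american] <- "native_american"
  keep <- is.na(rule)
  exclusions <- tibble::tibble(
    county_id = data$county_id[!keep],
    rule = rule[!keep]
  )
  report <- structure(list(
    n_input = nrow(data), n_output = sum(keep),
    exclusions = exclusions,
    thresholds = qc
  ), class = "filter_report")
  list(counties = data[keep, , drop = FALSE], report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report> %d -> %d counties (%d excluded)\n",
              x$n_input, x$n_output, nrow(x$exclusions)))
  if (nrow(x$exclusions) > 0) print(table(x$exclusions$rule))
  invisible(x)
}

#' Divergence diagnostic for exclusion-threshold selection
#'
#' Fits a weighted model of all-site cancer incidence on a fixed set of
#' demographic and health covariates (the exposure is deliberately
#' excluded so thresholds cannot be chosen opportunistically) and examines
#' how the absolute weighted residuals trend against a screening variable
#' such as Native American composition or the immigration rate. The trend
#' summary is the mean absolute weighted residual within equal-count bins
#' of the screening variable.
#'
#' @inheritParams fit_wols
#' @param screen_var Screening variable to bin against.
#' @param covariates Adjustment covariates; defaults to the eight
#'   demographic/health covariates used by the all-site model.
#' @param outcome All-site incidence column (default `all_site`).
#' @param bins Number of equal-count bins (default 10; a constant
#'   screening variable collapses to a single bin).
#' @return A `divergence_diagnostic` object: per-county `points`
#'   (`county_id`, screening value, `abs_resid` = `sqrt(w) * |residual|`),
#'   the binned `trend`, and the underlying `wols_fit`.
#' @export
divergence_diagnostic <- function(data, screen_var,
                                  covariates = diagnostic_covariates(),
                                  outcome = "all_site", weights = NULL,
                                  bins = 10, weight_cap = 250000) {
  if (is.null(weights)) {
    weights <- weights_from_population(data$population, cap = weight_cap)
  }
  used <- stats::complete.cases(
    data[, c(outcome, covariates, screen_var), drop = FALSE])
  df_cc <- data[used, , drop = FALSE]
  w <- weights[used]
  fit <- fit_wols(df_cc, outcome, covariates, weights = w)
  points <- tibble::tibble(
    county_id = df_cc$county_id,
    screen = df_cc[[screen_var]],
    abs_resid = sqrt(fit$weights) * abs(fit$residuals)
  )
  n_bins <- min(bins, length(unique(points$screen)))
  points$bin <- if (n_bins == 1) 1L else
    dplyr::ntile(points$screen, n_bins)
  trend <- points |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      screen_mid = stats::median(.data$screen),
      mean_abs_resid = mean(.data$abs_resid),
      n = dplyr::n(), .groups = "drop"
    )
  structure(list(points = points, trend = trend, fit = fit,
                 screen_var = screen_var),
            class = "divergence_diagnostic")
}

#' @export
print.divergence_diagnostic <- function(x, ...) {
  cat(sprintf("<divergence_diagnostic> screen: %s | n = %d\n",
              x$screen_var, nrow(x$points)))
  print(x$trend)
  invisible(x)
}
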