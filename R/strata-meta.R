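#' Tercile stratification of counties
#'
#' Cutpoints are the 1/3 and 2/3 empirical quantiles (type-7 interpolation)
#' of the stratifying variable; values exactly on a cutpoint go to the
#' lower stratum.
#'
#' @param data County tibble.
#' @param variable Column to stratify on.
#' @return A `strata` object: `cutpoints` and an `assignments` tibble with
#'   `county_id`, the variable value, and `stratum`
#'   (`low` / `mid` / `high`, missing value = `NA`).
#' @export
tercile_stratify <- function(data, variable) {
  x <- data[[variable]]
  if (is.null(x)) stop("variable not in data: ", variable, call. = FALSE)
  if (length(unique(stats::na.omit(x))) < 3) {
    stop("need at least 3 distinct values to form terciles", call. = FALSE)
  }
  q <- stats::quantile(x, c(1 / 3, 2 / 3), na.rm = TRUE, type = 7,
                       names = FALSE)
  if (q[1] >= q[2]) stop("degenerate tercile cutpoints", call. = FALSE)
  stratum <- dplyr::case_when(
    is.na(x) ~ NA_character_,
    x <= q[1] ~ "low",
    x <= q[2] ~ "mid",
    TRUE ~ "high"
  )
  structure(list(
    variable = variable,
    cutpoints = q,
    assignments = tibble::tibble(
      county_id = data$county_id, value = x,
      stratum = factor(stratum, levels = c("low", "mid", "high"))
    )
  ), class = "strata")
}

#' @export
print.strata <- function(x, ...) {
  cat(sprintf("<strata> %s terciles | cutpoints %.3f / %.3f\n",
              x$variable, x$cutpoints[1], x$cutpoints[2]))
  print(table(x$assignments$stratum))
  invisible(x)
}

#' Interaction test between two standardized predictors
#'
#' Refits the weighted model with the product of the two weighted
#' z-scored predictors appended as an extra term (named
#' `<var1>_x_<var2>`), and reports its coefficient and two-sided p-value.
#'
#' @inheritParams fit_wols
#' @param var1,var2 Names of the two interacting covariates (both must be
#'   in `covariates`).
#' @return A `wols_fit` including the product term.
#' @export
interaction_test <- function(data, outcome, covariates, var1, var2,
                             weights = NULL, ci_level = 0.99,
                             weight_cap = 250000) {
  stopifnot(var1 %in% covariates, var2 %in% covariates)
  if (is.null(weights)) {
    weights <- weights_from_population(data$population, cap = weight_cap)
  }
  used <- stats::complete.cases(data[, c(outcome, covariates), drop = FALSE])
  df_cc <- data[used, , drop = FALSE]
  w <- weights[used]
  term <- paste0(var1, "_x_", var2)
  df_cc[[term]] <- weighted_zscore(df_cc[[var1]], w) *
    weighted_zscore(df_cc[[var2]], w)
  fit_wols(df_cc, outcome, c(covariates, term), weights = w,
           ci_level = ci_level)
}

#' Fixed-effects (inverse-variance) meta-analysis with I-squared
#'
#' Pools per-stratum estimates with weights `1 / SE^2` under a
#' common-effect assumption. Heterogeneity is summarised by Cochran's Q and
#' `I2 = max(0, 100 * (Q - df) / Q)`; the 95% confidence interval for I2 is
#' obtained by the Q-profile method (inverting the generalised Q statistic
#' over the between-stratum variance, mapped to the I2 scale through the
#' typical within-stratum variance).
#'
#' @param estimates Data frame with columns `estimate` and `se` (one row
#'   per stratum); optional `label` and `n` columns are carried through.
#' @param ci_level Confidence level for the pooled estimate (default 0.99).
#' @return A `meta_result` object.
#' @export
fixed_effects_meta <- function(estimates, ci_level = 0.99) {
  stopifnot(is.data.frame(estimates),
            all(c("estimate", "se") %in% names(estimates)))
  if (any(estimates$se <= 0)) stop("standard errors must be positive",
                                   call. = FALSE)
  b <- estimates$estimate
  v <- estimates$se^2
  wt <- 1 / v
  pooled <- sum(wt * b) / sum(wt)
  pooled_se <- sqrt(1 / sum(wt))
  k <- length(b)
  q <- sum(wt * (b - pooled)^2)
  dfq <- k - 1
  i2 <- if (dfq == 0 || q <= 0) 0 else max(0, 100 * (q - dfq) / q)
  z <- stats::qnorm(1 - (1 - ci_level) / 2)

  i2_ci <- c(NA_real_, NA_real_)
  if (dfq >= 1) {
    # typical within-stratum variance (Higgins-Thompson s^2)
    s2 <- dfq * sum(wt) / (sum(wt)^2 - sum(wt^2))
    gen_q <- function(tau2) {
      wi <- 1 / (v + tau2)
      mu <- sum(wi * b) / sum(wi)
      sum(wi * (b - mu)^2)
    }
    tau2_at <- function(target) {
      if (gen_q(0) <= target) return(0)
      upper <- s2
      while (gen_q(upper) > target && upper < 1e8 * max(v)) upper <- upper * 2
      stats::uniroot(function(t2) gen_q(t2) - target, c(0, upper))$root
    }
    tau2_lo <- tau2_at(stats::qchisq(0.975, dfq))
    tau2_hi <- tau2_at(stats::qchisq(0.025, dfq))
    i2_ci <- 100 * c(tau2_lo / (tau2_lo + s2), tau2_hi / (tau2_hi + s2))
  }

  structure(list(
    strata = tibble::as_tibble(estimates),
    pooled = pooled, pooled_se = pooled_se,
    conf_low = pooled - z * pooled_se,
    conf_high = pooled + z * pooled_se,
    q = q, df = dfq,
    p_q = if (dfq > 0) stats::pchisq(q, dfq, lower.tail = FALSE) else NA_real_,
    i2 = i2, i2_conf = i2_ci,
    ci_level = ci_level
  ), class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf(
    "<meta_result> %d strata | pooled %.3f [%.3f, %.3f] (%.0f%% CI)\n Q = %.2f (df %d, p = %.3g), I2 = %.1f%% [%.1f, %.1f]\n",
    nrow(x$strata), x$pooled, x$conf_low, x$conf_high, 100 * x$ci_level,
    x$q, x$df, x$p_q, x$i2, x$i2_conf[1], x$i2_conf[2]))
  invisible(x)
}

#' State-stratified exposure models pooled by meta-analysis
#'
#' Within each state, regresses the outcome on the exposure plus an
#' adjustment covariate (by default smoking), then pools the state-specific
#' exposure coefficients with [fixed_effects_meta()]. States with too few
#' complete cases to fit the three-parameter model are dropped with a
#' warning.
#'
#' @inheritParams fit_wols
#' @param exposure Exposure column name.
#' @param adjust Adjustment covariate(s) used within each state.
#' @return A `meta_result`; the per-state table carries `label` (state) and
#'   `n`.
#' @export
state_meta <- function(data, outcome, exposure = "elevation",
                       adjust = "smoking", weights = NULL, ci_level = 0.99,
                       weight_cap = 250000) {
  if (is.null(weights)) {
    weights <- weights_from_population(data$population, cap = weight_cap)
  }
  rows <- list()
  for (st in sort(unique(data$state))) {
    idx <- data$state == st
    df_s <- data[idx, , drop = FALSE]
    cc <- sum(stats::complete.cases(
      df_s[, c(outcome, exposure, adjust), drop = FALSE]))
    if (cc < length(adjust) + 3) {
      warning("state ", st, " skipped: too few complete cases", call. = FALSE)
      next
    }
    f <- fit_wols(df_s, outcome, c(exposure, adjust),
                  weights = weights[idx], ci_level = ci_level)
    co <- f$coefficients[f$coefficients$term == exposure, ]
    rows[[st]] <- tibble::tibble(label = st, estimate = co$estimate,
                                 se = co$std_error, n = f$n)
  }
  fixed_effects_meta(dplyr::bind_rows(rows), ci_level = ci_level)
}

#' Refit the optimal model on population-subgroup outcomes
#'
#' Fits the same covariate set against each subgroup-specific outcome
#' (males, females, under 65, 65 and over), restricted to counties with
#' complete data across all subgroup outcomes and the model predictors so
#' the four fits are directly comparable. Sex-specific smoking prevalence
#' replaces overall smoking in the male and female models when the named
#' columns are present.
#'
#' @inheritParams fit_wols
#' @param subgroups Named character vector mapping subgroup labels to
#'   outcome columns.
#' @param covariates Covariates of the (optimal) model, including the
#'   exposure.
#' @param exposure Exposure whose coefficient and partial R-squared are
#'   summarised.
#' @param smoking_map Named list mapping subgroup labels to a
#'   `c(from, to)` smoking-column swap.
#' @return A `subgroup_fits` object: `summary` tibble plus the per-subgroup
#'   `wols_fit` and `partial_fit` lists.
#' @export
subgroup_refit <- function(data, covariates, exposure = "elevation",
                           subgroups = c(male = "lung_male",
                                         female = "lung_female",
                                         under65 = "lung_under65",
                                         over65 = "lung_65plus"),
                           smoking_map = list(
                             male = c("smoking", "smoking_male"),
                             female = c("smoking", "smoking_female")),
                           weights = NULL, ci_level = 0.99,
                           weight_cap = 250000) {
  missing_cols <- setdiff(unname(subgroups), names(data))
  if (length(missing_cols) > 0) {
    stop("subgroup outcome column(s) missing: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (is.null(weights)) {
    weights <- weights_from_population(data$population, cap = weight_cap)
  }
  swap_cols <- unique(unlist(lapply(smoking_map, `[`, 2)))
  swap_cols <- intersect(swap_cols, names(data))
  need <- unique(c(unname(subgroups), covariates, swap_cols))
  used <- stats::complete.cases(data[, need, drop = FALSE])
  df_cc <- data[used, , drop = FALSE]
  w <- weights[used]

  fits <- list(); partials <- list(); rows <- list()
  for (lab in names(subgroups)) {
    covs <- covariates
    if (lab %in% names(smoking_map)) {
      mp <- smoking_map[[lab]]
      if (mp[1] %in% covs && mp[2] %in% names(df_cc)) {
        covs[covs == mp[1]] <- mp[2]
      }
    }
    f <- fit_wols(df_cc, subgroups[[lab]], covs, weights = w,
                  ci_level = ci_level)
    p <- partial_regression(df_cc, subgroups[[lab]], covs, exposure,
                            weights = w, ci_level = ci_level)
    co <- f$coefficients[f$coefficients$term == exposure, ]
    rows[[lab]] <- tibble::tibble(
      subgroup = lab, outcome = subgroups[[lab]], n = f$n,
      estimate = co$estimate, conf_low = co$conf_low,
      conf_high = co$conf_high, beta_z = co$beta_z,
      beta_z_low = co$beta_z_low, beta_z_high = co$beta_z_high,
      p_one = co$p_one, partial_r2 = p$partial_r2
    )
    fits[[lab]] <- f
    partials[[lab]] <- p
  }
  structure(list(summary = dplyr::bind_rows(rows), fits = fits,
                 partials = partials, exposure = exposure,
                 ci_level = ci_level),
            class = "subgroup_fits")
}

#' @export
print.subgroup_fits <- function(x, ...) {
  cat(sprintf("<subgroup_fits> exposure: %s\n", x$exposure))
  print(x$summary)
  invisible(x)
}
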