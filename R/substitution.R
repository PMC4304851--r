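#' Bayes factor from a BIC difference
#'
#' `K = exp(-delta_bic / 2)`. `K > 1` favours the candidate model (its BIC
#' is lower), `K = 1` marks equal support, and `log(K)` is linear in the
#' BIC difference with slope -1/2.
#'
#' @param delta_bic Candidate BIC minus reference BIC.
#' @return The approximate Bayes factor.
#' @export
bayes_factor <- function(delta_bic) {
  stopifnot(is.numeric(delta_bic), all(is.finite(delta_bic)))
  exp(-delta_bic / 2)
}

#' Environmental-substitution scan
#'
#' Replaces the forced exposure with each environmental candidate, re-runs
#' the forced best-subset search, and converts the change in optimal BIC to
#' a Bayes factor. For each candidate, both the candidate-forced and the
#' exposure-forced searches are computed on the intersection of complete
#' cases over the covariates, the exposure and that candidate, so the two
#' BICs are compared at identical `n` (BICs at different sample sizes are
#' not comparable).
#'
#' @inheritParams fit_wols
#' @param exposure The forced exposure to be replaced.
#' @param candidates Character vector of candidate replacement columns,
#'   disjoint from `covariates`.
#' @return A tibble, one row per candidate: optimal size/BIC, `delta_bic`,
#'   Bayes factor `k`, `log10_k`, the candidate's standardized coefficient
#'   in its optimal model, and `n`.
#' @export
substitution_scan <- function(data, outcome, covariates,
                              exposure = "elevation", candidates,
                              weights = NULL, ci_level = 0.99,
                              weight_cap = 250000) {
  overlap <- intersect(candidates, covariates)
  if (length(overlap) > 0) {
    stop("candidates must be disjoint from covariates: ",
         paste(overlap, collapse = ", "), call. = FALSE)
  }
  if (is.null(weights)) {
    weights <- weights_from_population(data$population, cap = weight_cap)
  }
  rows <- list()
  for (cand in candidates) {
    cols <- unique(c(outcome, covariates, exposure, cand))
    cc <- stats::complete.cases(data[, cols, drop = FALSE])
    df_cc <- data[cc, , drop = FALSE]
    w <- weights[cc]
    ref <- best_subset(df_cc, outcome, c(covariates, exposure),
                       forced = exposure, weights = w, ci_level = ci_level)
    sub <- best_subset(df_cc, outcome, c(covariates, cand),
                       forced = cand, weights = w, ci_level = ci_level)
    if (ref$n != sub$n) {
      stop("internal error: reference and candidate case sets differ",
           call. = FALSE)
    }
    delta <- sub$optimal$bic - ref$optimal$bic
    co <- sub$fit$coefficients[sub$fit$coefficients$term == cand, ]
    rows[[cand]] <- tibble::tibble(
      candidate = cand, n = sub$n,
      size = sub$optimal$size, bic = sub$optimal$bic,
      reference_bic = ref$optimal$bic,
      delta_bic = delta, k = bayes_factor(delta),
      log10_k = -delta / (2 * log(10)),
      beta_z = co$beta_z
    )
  }
  dplyr::bind_rows(rows)
}

#' Confounding triplet for an exposure-correlated variable
#'
#' Fits the three lung-cancer models used to probe whether a variable's
#' apparent association is confounded by the exposure: (1) the variable
#' plus smoking; (2) the variable, smoking and the exposure; (3) the
#' variable plus the optimal best-subset predictors. Reports the variable's
#' standardized coefficient with a 95% interval and the one-tailed p-value
#' for negativity.
#'
#' @inheritParams fit_wols
#' @param variable The candidate confounded variable (e.g. radon or UVB).
#' @param smoking,exposure Column names of the smoking and exposure
#'   adjusters.
#' @param subset_covariates Covariates of the optimal best-subset model
#'   (typically including the exposure).
#' @param ci_level Interval level for the reported coefficients
#'   (default 0.95, the convention for this table).
#' @return A list with `summary` (tibble, one row per model) and `fits`.
#' @export
confounding_triplet <- function(data, outcome, variable,
                                smoking = "smoking",
                                exposure = "elevation",
                                subset_covariates,
                                weights = NULL, ci_level = 0.95,
                                weight_cap = 250000) {
  if (is.null(weights)) {
    weights <- weights_from_population(data$population, cap = weight_cap)
  }
  models <- list(
    model1 = c(variable, smoking),
    model2 = c(variable, smoking, exposure),
    model3 = unique(c(variable, subset_covariates))
  )
  fits <- lapply(models, function(covs) {
    fit_wols(data, outcome, covs, weights = weights, ci_level = ci_level)
  })
  summary <- purrr::imap_dfr(fits, function(f, nm) {
    co <- f$coefficients[f$coefficients$term == variable, ]
    tibble::tibble(model = nm, variable = variable, n = f$n,
                   beta_z = co$beta_z, beta_z_low = co$beta_z_low,
                   beta_z_high = co$beta_z_high, p_one = co$p_one)
  })
  list(summary = summary, fits = fits)
}
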