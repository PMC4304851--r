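#' Exhaustive best-subset search with a forced covariate
#'
#' For each model size from `length(forced)` up to the full covariate count,
#' enumerates every subset that contains the forced covariate(s) and keeps
#' the one minimising the weighted residual sum of squares; the optimal
#' model across sizes minimises BIC. Ties in BIC are broken toward the
#' smaller size, then lexicographic member order. Exhaustive enumeration is
#' exact and instantaneous at the scale this pipeline targets (at most 12
#' free covariates, i.e. 4096 fits).
#'
#' @inheritParams fit_wols
#' @param forced Covariate name(s) included in every candidate subset.
#' @return A `subset_scan` object with the per-size trace (`sizes`), the
#'   optimal record (`optimal`), and the optimal model refit as a
#'   `wols_fit` (`fit`).
#' @export
best_subset <- function(data, outcome, covariates, forced, weights = NULL,
                        ci_level = 0.99, weight_cap = 250000) {
  if (length(forced) == 0) stop("`forced` must be non-empty", call. = FALSE)
  if (!all(forced %in% covariates)) covariates <- union(forced, covariates)
  free <- setdiff(covariates, forced)
  if (length(covariates) > 25) {
    stop("exhaustive search limited to 25 covariates", call. = FALSE)
  }
  if (is.null(weights)) {
    weights <- weights_from_population(data$population, cap = weight_cap)
  }
  used <- stats::complete.cases(data[, c(outcome, covariates), drop = FALSE])
  df_cc <- data[used, , drop = FALSE]
  w <- weights[used]
  y <- df_cc[[outcome]]
  n <- length(y)
  sw <- sqrt(w)
  Xall <- as.matrix(df_cc[, covariates, drop = FALSE])
  Xw <- cbind(1, Xall) * sw
  colnames(Xw) <- c("(Intercept)", covariates)
  yw <- y * sw

  rss_of <- function(members) {
    cols <- c("(Intercept)", members)
    f <- stats::lm.fit(Xw[, cols, drop = FALSE], yw)
    if (f$rank < length(cols)) return(NA_real_)  # rank-deficient: skip
    sum(f$residuals^2)
  }

  records <- list()
  for (s in seq(length(forced), length(covariates))) {
    m <- s - length(forced)
    combos <- if (m == 0) list(character(0)) else
      utils::combn(free, m, simplify = FALSE)
    best_rss <- Inf
    best_members <- NULL
    skipped <- 0L
    for (extra in combos) {
      members <- c(forced, sort(extra))
      rss <- rss_of(members)
      if (is.na(rss)) { skipped <- skipped + 1L; next }
      if (rss < best_rss ||
          (rss == best_rss && !is.null(best_members) &&
           paste(members, collapse = ",") <
             paste(best_members, collapse = ","))) {
        best_rss <- rss
        best_members <- members
      }
    }
    if (skipped > 0) {
      warning(sprintf("size %d: skipped %d rank-deficient subset(s)", s,
                      skipped), call. = FALSE)
    }
    if (is.null(best_members)) {
      stop("all subsets rank-deficient at size ", s, call. = FALSE)
    }
    records[[length(records) + 1]] <- tibble::tibble(
      size = s, members = list(best_members), rss_w = best_rss,
      bic = wols_bic(best_rss, n, s)
    )
  }
  sizes <- dplyr::bind_rows(records)
  # BIC argmin; ties toward smaller size then lexicographic member order
  ord <- order(sizes$bic, sizes$size,
               vapply(sizes$members, paste, "", collapse = ","))
  optimal <- sizes[ord[1], ]
  fit <- fit_wols(df_cc, outcome, optimal$members[[1]], weights = w,
                  ci_level = ci_level)

  structure(list(
    outcome = outcome, forced = forced, covariates = covariates,
    n = n, sizes = sizes, optimal = optimal, fit = fit,
    ci_level = ci_level
  ), class = "subset_scan")
}

#' @export
print.subset_scan <- function(x, ...) {
  cat(sprintf(
    "<subset_scan> %s | forced: %s | n = %d\n optimal size %d (BIC %.1f): %s\n",
    x$outcome, paste(x$forced, collapse = ", "), x$n, x$optimal$size,
    x$optimal$bic, paste(x$optimal$members[[1]], collapse = ", ")))
  invisible(x)
}
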