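#' Run the full county analysis pipeline
#'
#' Sequences the whole analysis over a county table: quality-control
#' filtering; per-cancer forced-exposure best-subset selection, lasso with
#' cross-validation, and partial regression; the weighted predictor
#' correlation matrix; lung-specific stratifications (smoking terciles,
#' smoking-by-exposure interaction, state-stratified models pooled by
#' fixed-effects meta-analysis, population-subgroup refits when subgroup
#' outcome columns are present); environmental substitution scans for lung
#' and breast; and the radon/UVB confounding triplets.
#'
#' Every stochastic stage (only the lasso fold assignment) draws its seed
#' from `seed`, so two runs with the same inputs and seed are identical.
#'
#' @param counties County tibble (as from [read_county_table()] or
#'   [simulate_counties()]).
#' @param config An `analysis_config`.
#' @param seed Integer seed for the lasso cross-validation folds.
#' @param cor_method Correlation flavour for the predictor matrix,
#'   `"pearson"` (default) or `"spearman"`.
#' @return An `elevox_report` list: `filter`, per-cancer `subset`, `lasso`,
#'   `partial`, the `table2`/`table3`-shaped summary tibbles, `meta`,
#'   `interaction`, `terciles`, `subgroups`, `substitution`, `triplets`,
#'   `correlation`, and a `manifest` of seeds and row counts.
#' @export
run_all <- function(counties, config = default_config(), seed = 1L,
                    cor_method = c("pearson", "spearman")) {
  cor_method <- match.arg(cor_method)
  validate_county_table(counties)
  flt <- filter_counties(counties, config)
  dat <- flt$counties
  exposure <- config$exposure
  w <- weights_from_population(dat$population, cap = config$weight_cap)

  # cancer-specific datasets: complete cases over every included variable,
  # so each cancer's fits (selection, lasso, partial regression, and the
  # lung stratifications) share one case set
  datasets <- list(); dataset_w <- list()
  for (cancer in names(config$cancers)) {
    cols <- c(cancer, config$cancers[[cancer]], exposure)
    cc <- stats::complete.cases(dat[, cols, drop = FALSE])
    datasets[[cancer]] <- dat[cc, , drop = FALSE]
    dataset_w[[cancer]] <- w[cc]
  }

  subset_fits <- list(); lasso_fits <- list(); partials <- list()
  table2 <- list(); table3 <- list()
  for (cancer in names(config$cancers)) {
    covs <- config$cancers[[cancer]]
    dat_c <- datasets[[cancer]]
    w_c <- dataset_w[[cancer]]
    scan <- best_subset(dat_c, cancer, c(covs, exposure), forced = exposure,
                        weights = w_c, ci_level = config$ci_level)
    las <- cv_lasso(dat_c, cancer, c(covs, exposure), weights = w_c,
                    nfolds = config$lasso$nfolds, seed = seed,
                    n_lambda = config$lasso$n_lambda,
                    lambda_min_ratio = config$lasso$lambda_min_ratio)
    par <- partial_regression(dat_c, cancer, scan$optimal$members[[1]],
                              exposure, weights = w_c,
                              ci_level = config$ci_level)
    subset_fits[[cancer]] <- scan
    lasso_fits[[cancer]] <- las
    partials[[cancer]] <- par

    co <- scan$fit$coefficients[scan$fit$coefficients$term == exposure, ]
    table2[[cancer]] <- tibble::tibble(
      cancer = cancer,
      mean_incidence = scan$fit$weighted_mean_y,
      sd_incidence = scan$fit$weighted_sd_y,
      n = scan$n, size = scan$optimal$size,
      r_squared = scan$fit$r_squared,
      p_value = co$p_one, beta = co$estimate, beta_z = co$beta_z,
      beta_pct = co$beta_pct,
      conf_low = co$conf_low, conf_high = co$conf_high,
      significant = co$p_one < config$bonferroni_alpha
    )
    lc <- las$coefficients[las$coefficients$term == exposure, ]
    table3[[cancer]] <- tibble::tibble(
      cancer = cancer, size = las$size, r_squared = las$r_squared,
      beta = ifelse(lc$beta_z != 0, lc$estimate, NA_real_),
      beta_z = ifelse(lc$beta_z != 0, lc$beta_z, NA_real_),
      beta_pct = ifelse(lc$beta_z != 0, lc$beta_pct, NA_real_)
    )
  }

  pred_cols <- intersect(
    unique(c(unlist(config$cancers), exposure, config$env_candidates,
             names(config$cancers))), names(dat))
  correlation <- weighted_cor(dat[, pred_cols], w, method = cor_method)

  # lung stratifications run on the lung dataset
  lung_members <- subset_fits$lung$optimal$members[[1]]
  dat_l <- datasets$lung
  w_l <- dataset_w$lung
  terciles <- tercile_stratify(dat_l, "smoking")
  interaction <- interaction_test(dat_l, "lung",
                                  union(lung_members, c("smoking", exposure)),
                                  "smoking", exposure, weights = w_l,
                                  ci_level = config$ci_level)
  meta <- state_meta(dat_l, "lung", exposure = exposure, adjust = "smoking",
                     weights = w_l, ci_level = config$ci_level)
  subgroups <- NULL
  if (all(c("lung_male", "lung_female", "lung_under65", "lung_65plus")
          %in% names(dat))) {
    subgroups <- subgroup_refit(dat, lung_members, exposure = exposure,
                                weights = w, ci_level = config$ci_level)
  }

  # lung substitutions: radon and particulate leave the covariate set and
  # join the candidate list
  lung_sub_covs <- setdiff(config$cancers$lung, c("radon", "particulate"))
  substitution <- list(
    lung = substitution_scan(dat, "lung", lung_sub_covs,
                             exposure = exposure,
                             candidates = config$env_candidates,
                             weights = w, ci_level = config$ci_level),
    breast = substitution_scan(
      dat, "breast", setdiff(config$cancers$breast, config$env_candidates),
      exposure = exposure, candidates = config$env_candidates,
      weights = w, ci_level = config$ci_level)
  )
  triplets <- list(
    radon = confounding_triplet(dat_l, "lung", "radon",
                                subset_covariates = lung_members,
                                weights = w_l),
    uvb = confounding_triplet(dat_l, "lung", "uvb",
                              subset_covariates = lung_members,
                              weights = w_l)
  )

  structure(list(
    filter = flt$report,
    counties = dat,
    subset = subset_fits, lasso = lasso_fits, partial = partials,
    table2 = dplyr::bind_rows(table2), table3 = dplyr::bind_rows(table3),
    correlation = correlation,
    terciles = terciles, interaction = interaction, meta = meta,
    subgroups = subgroups, substitution = substitution,
    triplets = triplets,
    manifest = list(
      seed = seed, ci_level = config$ci_level,
      n_input = flt$report$n_input, n_filtered = flt$report$n_output,
      n_per_cancer = vapply(subset_fits, function(s) s$n, 0L),
      cor_method = cor_method
    )
  ), class = "elevox_report")
}

#' @export
print.elevox_report <- function(x, ...) {
  cat("<elevox_report>\n")
  cat(sprintf(" counties: %d -> %d after QC\n", x$manifest$n_input,
              x$manifest$n_filtered))
  cat(" optimal best-subset models:\n")
  print(x$table2[, c("cancer", "n", "size", "r_squared", "beta", "beta_z",
                     "p_value")])
  cat(sprintf(" state meta-analysis: pooled %.2f [%.2f, %.2f], I2 = %.0f%%\n",
              x$meta$pooled, x$meta$conf_low, x$meta$conf_high, x$meta$i2))
  invisible(x)
}

#' Write the report bundle as tab-delimited tables
#'
#' Emits one TSV per report surface (optimal-model summary, lasso summary,
#' per-size BIC traces, meta-analysis strata, substitution scans,
#' confounding triplets, correlation matrix, exclusion list) into a
#' directory.
#'
#' @param report An `elevox_report` from [run_all()].
#' @param dir Output directory (created if absent).
#' @return The directory path, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "elevox_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  out <- function(x, name) {
    readr::write_tsv(x, file.path(dir, paste0(name, ".tsv")), na = "")
  }
  out(report$table2, "best_subset_summary")
  out(report$table3, "lasso_summary")
  traces <- purrr::imap_dfr(report$subset, function(s, cancer) {
    dplyr::mutate(
      tidy(s), cancer = cancer, .before = 1)
  })
  out(traces, "bic_traces")
  out(tidy(report$meta), "state_meta_strata")
  out(glance(report$meta), "state_meta_pooled")
  out(dplyr::bind_rows(report$substitution, .id = "cancer"),
      "substitution_scan")
  out(dplyr::bind_rows(lapply(report$triplets, `[[`, "summary"),
                       .id = "variable"), "confounding_triplets")
  if (!is.null(report$subgroups)) out(report$subgroups$summary, "subgroups")
  out(report$filter$exclusions, "qc_exclusions")
  cor_tbl <- tibble::as_tibble(report$correlation, rownames = "variable")
  out(cor_tbl, "correlation_matrix")
  invisible(dir)
}
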