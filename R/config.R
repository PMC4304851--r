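#' Default analysis configuration
#'
#' Bundles every tunable the pipeline uses: the per-cancer covariate sets,
#' the forced exposure, the weight cap, the county quality-control
#' thresholds, the confidence level, lasso cross-validation settings, and
#' the Bonferroni-adjusted one-tailed significance cutoff (0.05 / 4 cancers).
#'
#' Thresholds are expressed in the same units as the table columns:
#' population in persons, immigration and Native American composition in
#' percent.
#'
#' @return An object of class `analysis_config` (a named list).
#' @export
default_config <- function() {
  cfg <- list(
    exposure = "elevation",
    cancers = covariate_sets()[c("lung", "breast", "colorectal", "prostate")],
    env_candidates = covariate_sets()$env,
    weight_cap = 250000,
    qc = list(
      states = western_states(),
      min_population = 10000,
      max_immigration = 40,
      max_native_american = 25
    ),
    ci_level = 0.99,
    lasso = list(nfolds = 10, rule = "one_se", n_lambda = 100,
                 lambda_min_ratio = 0.001, seed = 1L),
    bonferroni_alpha = 0.0125
  )
  structure(cfg, class = "analysis_config")
}

#' Load an analysis configuration from YAML or JSON
#'
#' Fields absent from the file keep their defaults from [default_config()].
#' Cancer keys and covariate names are validated against the variable
#' registry; an unknown name is a configuration error.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An `analysis_config` object.
#' @export
load_analysis_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  user <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  cfg <- unclass(default_config())
  for (key in names(user)) {
    if (!key %in% names(cfg)) {
      stop("unknown configuration key: ", key, call. = FALSE)
    }
    if (is.list(cfg[[key]]) && is.list(user[[key]]) && key != "cancers") {
      for (sub in names(user[[key]])) {
        if (!sub %in% names(cfg[[key]])) {
          stop("unknown configuration key: ", key, "$", sub, call. = FALSE)
        }
        cfg[[key]][[sub]] <- user[[key]][[sub]]
      }
    } else {
      cfg[[key]] <- user[[key]]
    }
  }
  validate_config(structure(cfg, class = "analysis_config"))
}

validate_config <- function(cfg) {
  known <- county_registry()$variable
  for (cancer in names(cfg$cancers)) {
    bad <- setdiff(cfg$cancers[[cancer]], known)
    if (length(bad) > 0) {
      stop("unknown covariate(s) for ", cancer, ": ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    if (!cancer %in% c("lung", "breast", "colorectal", "prostate")) {
      stop("unknown cancer key: ", cancer, call. = FALSE)
    }
  }
  if (!is.numeric(cfg$ci_level) || cfg$ci_level <= 0 || cfg$ci_level >= 1) {
    stop("ci_level must lie strictly between 0 and 1", call. = FALSE)
  }
  if (cfg$weight_cap <= 0) stop("weight_cap must be positive", call. = FALSE)
  cfg
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("<analysis_config>\n")
  cat("  exposure:", x$exposure, "\n")
  for (cancer in names(x$cancers)) {
    cat(sprintf("  %s: %d covariates + %s\n", cancer,
                length(x$cancers[[cancer]]), x$exposure))
  }
  cat("  weight cap:", x$weight_cap, " ci:", x$ci_level,
      " bonferroni:", x$bonferroni_alpha, "\n")
  cat("  qc: states =", length(x$qc$states),
      "| min pop", x$qc$min_population,
      "| immigration >", x$qc$max_immigration,
      "| native >", x$qc$max_native_american, "\n")
  invisible(x)
}
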