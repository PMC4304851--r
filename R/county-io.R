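#' Read a tab-delimited county table
#'
#' Reads the tab-delimited county-data dialect used by this pipeline: one
#' header row, one county per row, blank cells meaning missing (never zero),
#' and source-reported 95% confidence bounds stored in columns whose names
#' append `lower`/`upper` to the variable name. Headers are normalised to
#' the canonical lowercase snake_case registry names, and `<var>lower` /
#' `<var>upper` are rewritten to `<var>_lower` / `<var>_upper`. Unknown
#' extra columns are retained (and ignored by analyses). Numbers must use a
#' `.` decimal separator; thousands separators are rejected.
#'
#' @param path Path to a UTF-8, tab-delimited file with a header row.
#' @return A tibble with `county_id` and `state` as character and every
#'   other column numeric, missing values as `NA`.
#' @export
read_county_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- suppressWarnings(readr::read_tsv(
    path, col_types = readr::cols(.default = readr::col_character()),
    na = "", progress = FALSE, show_col_types = FALSE
  ))
  if (ncol(raw) < 1 || nrow(raw) == 0 || any(is.na(names(raw))) ||
      any(grepl("^X\\d+$", names(raw)))) {
    stop("malformed county table: missing or incomplete header", call. = FALSE)
  }
  names(raw) <- normalize_header(names(raw))
  if (!"county_id" %in% names(raw)) {
    stop("malformed county table: no county_id column", call. = FALSE)
  }
  if (anyDuplicated(raw$county_id)) {
    dup <- unique(raw$county_id[duplicated(raw$county_id)])
    stop("duplicate county_id: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  keep_chr <- intersect(c("county_id", "state"), names(raw))
  for (col in setdiff(names(raw), keep_chr)) {
    vals <- raw[[col]]
    parsed <- suppressWarnings(as.numeric(vals))
    bad <- which(!is.na(vals) & is.na(parsed))
    if (length(bad) > 0) {
      stop(sprintf("non-numeric value '%s' in column '%s', row %d",
                   vals[bad[1]], col, bad[1]), call. = FALSE)
    }
    raw[[col]] <- parsed
  }
  if ("population" %in% names(raw) &&
      any(raw$population <= 0, na.rm = TRUE)) {
    stop("population must be positive where present", call. = FALSE)
  }
  raw
}

# Header normalisation: lowercase snake_case plus the supplementary-dataset
# convention of bare 'lower'/'upper' suffixes for CI bound columns.
normalize_header <- function(x) {
  x <- gsub("[ .-]+", "_", tolower(trimws(x)))
  x <- sub("^fips$", "county_id", x)
  known <- county_registry()$variable
  vapply(x, function(nm) {
    for (suf in c("lower", "upper")) {
      if (grepl(paste0(suf, "$"), nm) && !grepl(paste0("_", suf, "$"), nm)) {
        stem <- sub(paste0(suf, "$"), "", nm)
        if (stem %in% known) return(paste0(stem, "_", suf))
      }
    }
    nm
  }, character(1), USE.NAMES = FALSE)
}

#' Write a county table as tab-delimited text
#'
#' Missing values are written as blank cells, so a write/read round trip
#' preserves both values and the missingness mask.
#'
#' @param counties County tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_county_table <- function(counties, path) {
  readr::write_tsv(counties, path, na = "")
  invisible(path)
}

#' Extract source-reported confidence bounds
#'
#' Collects the `<var>_lower` / `<var>_upper` column pairs into a long
#' tibble, one row per county and variable.
#'
#' @param counties County tibble.
#' @return Tibble with columns `county_id`, `variable`, `lower`, `upper`.
#' @export
ci_bounds <- function(counties) {
  lows <- grep("_lower$", names(counties), value = TRUE)
  vars <- sub("_lower$", "", lows)
  vars <- vars[paste0(vars, "_upper") %in% names(counties)]
  purrr::map_dfr(vars, function(v) {
    tibble::tibble(
      county_id = counties$county_id,
      variable = v,
      lower = counties[[paste0(v, "_lower")]],
      upper = counties[[paste0(v, "_upper")]]
    )
  })
}

#' Validate county-table invariants
#'
#' Checks unique county ids and positive population. Invisibly returns the
#' table so it can be used in a pipe.
#'
#' @param counties County tibble.
#' @export
validate_county_table <- function(counties) {
  stopifnot(is.data.frame(counties))
  if (!"county_id" %in% names(counties)) stop("no county_id column", call. = FALSE)
  if (anyDuplicated(counties$county_id)) stop("duplicate county_id", call. = FALSE)
  if ("population" %in% names(counties) &&
      any(counties$population <= 0, na.rm = TRUE)) {
    stop("population must be positive where present", call. = FALSE)
  }
  invisible(counties)
}
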