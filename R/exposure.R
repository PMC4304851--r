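#' Create an in-memory exposure raster
#'
#' A lightweight single-band regular grid: a numeric matrix (row 1 is the
#' top of the grid, as in the ESRI ASCII grid convention), a lower-left
#' corner, a square cell size, and an optional no-data value.
#'
#' @param values Numeric matrix of cell values.
#' @param xll,yll Coordinates of the lower-left corner of the grid.
#' @param cellsize Side length of a (square) cell.
#' @param nodata Value marking missing cells (stored as `NA` internally).
#' @param crs Free-text coordinate reference system tag; zonal operations
#'   require raster and polygons to carry the same tag.
#' @return An `exposure_grid` object.
#' @export
exposure_grid <- function(values, xll = 0, yll = 0, cellsize = 1,
                          nodata = -9999, crs = "local") {
  stopifnot(is.matrix(values), cellsize > 0)
  values[values == nodata] <- NA_real_
  structure(list(values = values, xll = xll, yll = yll,
                 cellsize = cellsize, nodata = nodata, crs = crs),
            class = "exposure_grid")
}

#' @export
print.exposure_grid <- function(x, ...) {
  cat(sprintf(
    "<exposure_grid> %d x %d cells, cellsize %g, origin (%g, %g), crs %s\n",
    nrow(x$values), ncol(x$values), x$cellsize, x$xll, x$yll, x$crs))
  invisible(x)
}

# Cell-center coordinates of a grid, as vectors aligned with the
# column-major flattening of the value matrix.
grid_centers <- function(grid) {
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  cx <- grid$xll + (seq_len(nc) - 0.5) * grid$cellsize
  cy <- grid$yll + (nr - seq_len(nr) + 0.5) * grid$cellsize
  list(x = rep(cx, each = nr), y = rep(cy, times = nc),
       value = as.vector(grid$values))
}

#' Read and write ESRI ASCII grid rasters
#'
#' The ASCII grid (`.asc`) format stores the six-line header
#' (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`,
#' `NODATA_value`) followed by rows of cell values from the top of the grid
#' down.
#'
#' @param path File path.
#' @return [read_ascii_grid()] returns an `exposure_grid`;
#'   [write_ascii_grid()] returns `path` invisibly.
#' @export
read_ascii_grid <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr))) {
    stop("malformed ASCII grid header", call. = FALSE)
  }
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows) {
    stop("ASCII grid value count does not match header dimensions",
         call. = FALSE)
  }
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  exposure_grid(m, xll = hdr$xllcorner, yll = hdr$yllcorner,
                cellsize = hdr$cellsize, nodata = nodata)
}

#' @rdname read_ascii_grid
#' @param grid An `exposure_grid`.
#' @export
write_ascii_grid <- function(grid, path) {
  stopifnot(inherits(grid, "exposure_grid"))
  vals <- grid$values
  vals[is.na(vals)] <- grid$nodata
  hdr <- c(
    paste("ncols", ncol(vals)), paste("nrows", nrow(vals)),
    paste("xllcorner", format(grid$xll, scientific = FALSE)),
    paste("yllcorner", format(grid$yll, scientific = FALSE)),
    paste("cellsize", format(grid$cellsize, scientific = FALSE)),
    paste("NODATA_value", format(grid$nodata, scientific = FALSE))
  )
  body <- apply(vals, 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

# Even-odd ray-casting point-in-polygon test, vectorised over points.
# Boundary handling follows the classic crossing rule, which assigns a
# point lying on an edge shared by two tiling polygons to exactly one of
# them (the lower-left-inclusive, half-open convention): refining a
# partition never counts a cell center twice or drops it.
points_in_ring <- function(px, py, ring) {
  rx <- ring[, 1]; ry <- ring[, 2]
  nv <- length(rx)
  inside <- rep(FALSE, length(px))
  j <- nv
  for (i in seq_len(nv)) {
    crosses <- ((ry[i] > py) != (ry[j] > py))
    if (any(crosses)) {
      xint <- rx[i] + (py[crosses] - ry[i]) / (ry[j] - ry[i]) *
        (rx[j] - rx[i])
      inside[crosses] <- xor(inside[crosses], px[crosses] < xint)
    }
    j <- i
  }
  inside
}

#' Unweighted zonal mean of a raster over one polygon
#'
#' Averages the values of all cells whose center falls inside the polygon
#' (even-odd rule with half-open boundary handling, so polygons tiling a
#' region claim each cell center exactly once), ignoring no-data cells.
#'
#' @param grid An `exposure_grid`.
#' @param ring Polygon ring: a two-column matrix of vertex coordinates
#'   (closed or open; the ring is closed implicitly).
#' @return A list with `mean` and `n_cells`. A polygon containing no cell
#'   centers is an error (callers may fall back to the nearest cell).
#' @export
zonal_mean <- function(grid, ring) {
  stopifnot(inherits(grid, "exposure_grid"))
  ring <- as.matrix(ring)
  ctr <- grid_centers(grid)
  bb <- c(range(ring[, 1]), range(ring[, 2]))
  cand <- ctr$x >= bb[1] & ctr$x <= bb[2] & ctr$y >= bb[3] & ctr$y <= bb[4]
  if (!any(cand)) stop("empty zone: polygon contains no cell centers",
                       call. = FALSE)
  hit <- cand
  hit[cand] <- points_in_ring(ctr$x[cand], ctr$y[cand], ring)
  vals <- ctr$value[hit]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) stop("empty zone: polygon contains no cell centers",
                              call. = FALSE)
  list(mean = mean(vals), n_cells = length(vals))
}

#' Population-weighted average of subunit exposures
#'
#' @param values Subunit mean exposures.
#' @param populations Subunit populations (non-negative; zero-population
#'   subunits contribute nothing).
#' @return The population-weighted mean.
#' @export
population_weighted_exposure <- function(values, populations) {
  stopifnot(length(values) == length(populations))
  if (any(populations < 0)) stop("populations must be non-negative",
                                 call. = FALSE)
  keep <- populations > 0 & !is.na(values)
  if (sum(populations[keep]) == 0) {
    stop("undefined exposure: total subunit population is zero",
         call. = FALSE)
  }
  sum(values[keep] * populations[keep]) / sum(populations[keep])
}

#' County exposures from a raster and population-weighted subunits
#'
#' Computes the zonal mean of the raster over every subunit polygon, then
#' the population-weighted average of the subunit means within each county.
#' A subunit whose polygon captures no cell center falls back to the value
#' of the nearest cell, with a warning (small subunits against coarse
#' rasters are a realistic scenario).
#'
#' @param grid An `exposure_grid`.
#' @param subunits Tibble with `subunit_id`, `county_id`, `population`, a
#'   `geometry` list-column of polygon rings, and optionally a `crs`
#'   attribute matching the grid's.
#' @return Tibble of `county_id`, `weighted_exposure`, `n_subunits`.
#' @export
county_exposures <- function(grid, subunits) {
  stopifnot(inherits(grid, "exposure_grid"))
  sub_crs <- attr(subunits, "crs")
  if (!is.null(sub_crs) && !identical(sub_crs, grid$crs)) {
    stop("coordinate reference systems differ between raster (", grid$crs,
         ") and subunits (", sub_crs, ")", call. = FALSE)
  }
  ctr <- grid_centers(grid)
  means <- vapply(seq_len(nrow(subunits)), function(i) {
    ring <- subunits$geometry[[i]]
    tryCatch(zonal_mean(grid, ring)$mean, error = function(e) {
      warning("subunit ", subunits$subunit_id[i],
              ": no cell centers, using nearest cell", call. = FALSE)
      cx <- mean(range(ring[, 1])); cy <- mean(range(ring[, 2]))
      ok <- !is.na(ctr$value)
      d2 <- (ctr$x[ok] - cx)^2 + (ctr$y[ok] - cy)^2
      ctr$value[ok][which.min(d2)]
    })
  }, 0)
  tibble::tibble(county_id = subunits$county_id,
                 subunit_id = subunits$subunit_id,
                 population = subunits$population,
                 subunit_mean = means) |>
    dplyr::group_by(.data$county_id) |>
    dplyr::summarise(
      weighted_exposure = population_weighted_exposure(.data$subunit_mean,
                                                       .data$population),
      n_subunits = dplyr::n(), .groups = "drop"
    )
}

#' Read and write subunit polygons as GeoJSON
#'
#' Subunits are Polygon features carrying `subunit_id`, `county_id` and
#' `population` properties. Only the exterior ring is used.
#'
#' @param path File path.
#' @return [read_subunits_geojson()] returns the subunit tibble with a
#'   `geometry` list-column; [write_subunits_geojson()] returns `path`
#'   invisibly.
#' @export
read_subunits_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection",
                                 call. = FALSE)
  rows <- purrr::map_dfr(gj$features, function(f) {
    tibble::tibble(
      subunit_id = as.character(f$properties$subunit_id),
      county_id = as.character(f$properties$county_id),
      population = as.numeric(f$properties$population),
      geometry = list(do.call(rbind, lapply(f$geometry$coordinates[[1]],
                                            function(pt) unlist(pt))))
    )
  })
  attr(rows, "crs") <- gj$crs$properties$name %||% "local"
  rows
}

#' @rdname read_subunits_geojson
#' @param subunits Subunit tibble as produced by
#'   [simulate_exposure_fixture()] or [read_subunits_geojson()].
#' @export
write_subunits_geojson <- function(subunits, path) {
  features <- lapply(seq_len(nrow(subunits)), function(i) {
    ring <- subunits$geometry[[i]]
    if (!all(ring[1, ] == ring[nrow(ring), ])) {
      ring <- rbind(ring, ring[1, ])
    }
    list(
      type = "Feature",
      properties = list(subunit_id = subunits$subunit_id[i],
                        county_id = subunits$county_id[i],
                        population = subunits$population[i]),
      geometry = list(type = "Polygon",
                      coordinates = list(lapply(seq_len(nrow(ring)),
                                                function(r) ring[r, ])))
    )
  })
  gj <- list(type = "FeatureCollection",
             crs = list(type = "name",
                        properties = list(name = attr(subunits, "crs") %||%
                                            "local")),
             features = features)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a raster-plus-subunits exposure fixture
#'
#' Builds a deterministic planar-gradient raster (value = `base` +
#' `gradient` * (x + y) + seeded noise) and, for each county, a horizontal
#' strip of the grid tiled into equal-width rectangular subunits with
#' seeded positive populations.
#'
#' @param n_counties Number of counties (one strip each).
#' @param subunits_per_county Rectangles tiling each county strip.
#' @param gradient Value change per unit step in x or y.
#' @param base Value at the grid origin.
#' @param noise_sd Standard deviation of seeded cell noise (0 for a
#'   deterministic field).
#' @param cells_per_subunit Width of each subunit in cells.
#' @param strip_height Height of each county strip in cells.
#' @param seed Integer seed.
#' @return A list of class `exposure_fixture`: `grid` (an
#'   `exposure_grid`) and `subunits` (tibble with geometry).
#' @export
simulate_exposure_fixture <- function(n_counties = 5,
                                      subunits_per_county = 4,
                                      gradient = 1, base = 100,
                                      noise_sd = 0,
                                      cells_per_subunit = 5,
                                      strip_height = 6, seed = 1L) {
  stopifnot(n_counties >= 1, subunits_per_county >= 1,
            cells_per_subunit >= 1, strip_height >= 1)
  set.seed(seed)
  nc <- subunits_per_county * cells_per_subunit
  nr <- n_counties * strip_height
  cx <- (seq_len(nc) - 0.5)
  cy <- (nr - seq_len(nr) + 0.5)
  field <- outer(cy, cx, function(y, x) base + gradient * (x + y))
  if (noise_sd > 0) field <- field + matrix(stats::rnorm(nr * nc, 0,
                                                         noise_sd), nr)
  grid <- exposure_grid(field, xll = 0, yll = 0, cellsize = 1)

  rows <- list()
  for (co in seq_len(n_counties)) {
    y0 <- (n_counties - co) * strip_height
    y1 <- y0 + strip_height
    for (su in seq_len(subunits_per_county)) {
      x0 <- (su - 1) * cells_per_subunit
      x1 <- su * cells_per_subunit
      rows[[length(rows) + 1]] <- tibble::tibble(
        subunit_id = sprintf("%03d-%02d", co, su),
        county_id = sprintf("%03d", co),
        population = stats::rpois(1, 1300) + 1,
        geometry = list(cbind(c(x0, x1, x1, x0, x0),
                              c(y0, y0, y1, y1, y0)))
      )
    }
  }
  subunits <- dplyr::bind_rows(rows)
  attr(subunits, "crs") <- "local"
  structure(list(grid = grid, subunits = subunits),
            class = "exposure_fixture")
}

#' @export
print.exposure_fixture <- function(x, ...) {
  cat(sprintf("<exposure_fixture> %d subunits over a %d x %d grid\n",
              nrow(x$subunits), nrow(x$grid$values), ncol(x$grid$values)))
  invisible(x)
}
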