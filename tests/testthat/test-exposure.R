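test_that("zonal means reduce to simple means on small grids", {
  const <- exposure_grid(matrix(1500, 4, 4))
  ring <- cbind(c(0.2, 3.1, 3.1, 0.2), c(0.3, 0.3, 3.6, 3.6))
  expect_equal(zonal_mean(const, ring)$mean, 1500)

  g <- exposure_grid(matrix(c(0, 200, 100, 300), 2, 2))  # rows top-down
  full <- cbind(c(0, 2, 2, 0), c(0, 0, 2, 2))
  z <- zonal_mean(g, full)
  expect_equal(z$mean, 150)
  expect_equal(z$n_cells, 4L)
})

test_that("zonal mean equals a brute-force cell-center scan", {
  set.seed(21)
  g <- exposure_grid(matrix(rnorm(2500), 50, 50))
  ctr_x <- rep((1:50) - 0.5, each = 50)
  ctr_y <- rep(rev((1:50) - 0.5), times = 50)
  vals <- as.vector(g$values)
  for (i in 1:10) {
    x0 <- runif(1, 0, 40) + 0.123; x1 <- x0 + runif(1, 2, 9)
    y0 <- runif(1, 0, 40) + 0.321; y1 <- y0 + runif(1, 2, 9)
    ring <- cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))
    inside <- ctr_x > x0 & ctr_x < x1 & ctr_y > y0 & ctr_y < y1
    expect_equal(zonal_mean(g, ring)$mean, mean(vals[inside]))
  }
})

test_that("ray casting agrees with pracma on interior points", {
  skip_if_not_installed("pracma")
  set.seed(22)
  ang <- sort(runif(7, 0, 2 * pi))
  ring <- cbind(5 + 4 * cos(ang), 5 + 4 * sin(ang))
  px <- runif(400, 0, 10); py <- runif(400, 0, 10)
  ours <- points_in_ring(px, py, ring)
  ref <- pracma::inpolygon(px, py, ring[, 1], ring[, 2], boundary = TRUE)
  expect_equal(ours, ref)
})

test_that("population weighting of subunit means is a weighted average", {
  expect_equal(population_weighted_exposure(c(100, 300), c(1000, 3000)), 250)
  expect_equal(population_weighted_exposure(c(10, 20, 30), rep(7, 3)), 20)
  # zero-population subunits are neutral
  expect_equal(population_weighted_exposure(c(100, 300, 9999),
                                            c(1000, 3000, 0)), 250)
  expect_error(population_weighted_exposure(c(1, 2), c(0, 0)), "undefined")
  expect_error(population_weighted_exposure(c(1, 2), c(-1, 2)),
               "non-negative")
})

test_that("county exposures reduce correctly in degenerate layouts", {
  # constant raster: every county's exposure equals the constant
  fx <- simulate_exposure_fixture(n_counties = 3, subunits_per_county = 4,
                                  gradient = 0, base = 42, seed = 2)
  expect_true(all(fx$grid$values == 42))
  ce <- county_exposures(fx$grid, fx$subunits)
  expect_equal(ce$weighted_exposure, rep(42, 3))

  # one county, one subunit covering the full raster: grand mean
  fx1 <- simulate_exposure_fixture(n_counties = 1, subunits_per_county = 1,
                                   gradient = 2, noise_sd = 1,
                                   cells_per_subunit = 12,
                                   strip_height = 8, seed = 3)
  ce1 <- county_exposures(fx1$grid, fx1$subunits)
  expect_equal(ce1$weighted_exposure, mean(fx1$grid$values))

  # same seed twice: identical fixtures
  expect_identical(simulate_exposure_fixture(seed = 4),
                   simulate_exposure_fixture(seed = 4))
})

test_that("refining the subunit partition leaves exposure unchanged", {
  fx <- simulate_exposure_fixture(n_counties = 4, subunits_per_county = 3,
                                  gradient = 1.5, base = 200,
                                  cells_per_subunit = 6, seed = 5)
  before <- county_exposures(fx$grid, fx$subunits)

  # split every subunit into equal halves at a cell boundary, halving the
  # population; first on a field constant within each subunit (strict
  # invariance), then on the smooth gradient (equal halves, exact too)
  nr <- nrow(fx$grid$values); nc <- ncol(fx$grid$values)
  col_band <- matrix(rep(ceiling((1:nc) / 6), each = nr), nr)
  row_band <- matrix(rep(ceiling((1:nr) / 6), times = nc), nr)
  gconst <- fx$grid
  gconst$values <- 100 * row_band + 10 * col_band
  base_exp <- county_exposures(gconst, fx$subunits)

  halves <- purrr::map_dfr(seq_len(nrow(fx$subunits)), function(i) {
    ring <- fx$subunits$geometry[[i]]
    xs <- range(ring[, 1]); ys <- range(ring[, 2])
    mid <- (xs[1] + xs[2]) / 2
    tibble::tibble(
      subunit_id = paste0(fx$subunits$subunit_id[i], c("a", "b")),
      county_id = rep(fx$subunits$county_id[i], 2),
      population = rep(fx$subunits$population[i] / 2, 2),
      geometry = list(
        cbind(c(xs[1], mid, mid, xs[1]), c(ys[1], ys[1], ys[2], ys[2])),
        cbind(c(mid, xs[2], xs[2], mid), c(ys[1], ys[1], ys[2], ys[2]))
      )
    )
  })
  attr(halves, "crs") <- "local"
  after <- county_exposures(gconst, halves)
  expect_equal(after$weighted_exposure, base_exp$weighted_exposure,
               tolerance = 1e-9)

  # and on the smooth gradient, splitting at the midpoint of an even-width
  # strip with equal populations is also exact
  after_grad <- county_exposures(fx$grid, halves)
  expect_equal(after_grad$weighted_exposure, before$weighted_exposure,
               tolerance = 1e-9)
})

test_that("exposure is bounded by the subunit means", {
  fx <- simulate_exposure_fixture(n_counties = 5, subunits_per_county = 4,
                                  gradient = 3, noise_sd = 5, seed = 6)
  sub_means <- vapply(seq_len(nrow(fx$subunits)), function(i) {
    zonal_mean(fx$grid, fx$subunits$geometry[[i]])$mean
  }, 0)
  ce <- county_exposures(fx$grid, fx$subunits)
  for (co in ce$county_id) {
    idx <- fx$subunits$county_id == co
    expect_gte(ce$weighted_exposure[ce$county_id == co], min(sub_means[idx]))
    expect_lte(ce$weighted_exposure[ce$county_id == co], max(sub_means[idx]))
  }
})

test_that("ASCII grid and GeoJSON round trips preserve the fixture", {
  fx <- simulate_exposure_fixture(n_counties = 2, subunits_per_county = 3,
                                  gradient = 0.7, noise_sd = 2, seed = 7)
  asc <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(fx$grid, asc)
  g2 <- read_ascii_grid(asc)
  expect_equal(g2$values, fx$grid$values, tolerance = 1e-12)
  expect_equal(g2$cellsize, fx$grid$cellsize)
  expect_equal(g2$xll, fx$grid$xll)

  gj <- withr::local_tempfile(fileext = ".geojson")
  write_subunits_geojson(fx$subunits, gj)
  s2 <- read_subunits_geojson(gj)
  expect_equal(s2$population, fx$subunits$population)
  expect_equal(s2$county_id, fx$subunits$county_id)
  ce1 <- county_exposures(fx$grid, fx$subunits)
  ce2 <- county_exposures(g2, s2)
  expect_equal(ce2$weighted_exposure, ce1$weighted_exposure,
               tolerance = 1e-9)
})

test_that("CRS mismatches and empty zones are handled", {
  fx <- simulate_exposure_fixture(seed = 8)
  bad <- fx$subunits
  attr(bad, "crs") <- "EPSG:32613"
  expect_error(county_exposures(fx$grid, bad), "reference system")

  # a sliver polygon between cell centers falls back to the nearest cell
  sliver <- tibble::tibble(
    subunit_id = "s", county_id = "001", population = 10,
    geometry = list(cbind(c(1.6, 1.9, 1.9, 1.6), c(1.6, 1.6, 1.9, 1.9)))
  )
  attr(sliver, "crs") <- "local"
  expect_warning(ce <- county_exposures(fx$grid, sliver), "nearest")
  expect_true(is.finite(ce$weighted_exposure))
  expect_error(zonal_mean(fx$grid, sliver$geometry[[1]]), "empty zone")
})
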