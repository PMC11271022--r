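# Coordinate parsing, projection, hulls, areas and grid indexing.

test_that("coordinate strings parse to signed decimal degrees", {
  expect_equal(parse_coordinate("41°51'04.4''N"), 41 + 51 / 60 + 4.4 / 3600,
               tolerance = 1e-9)
  expect_equal(parse_coordinate("42.818467"), 42.818467)
  expect_equal(parse_coordinate("09°26'E"), 9 + 26 / 60, tolerance = 1e-9)
  expect_equal(parse_coordinate("8°54'00.8\"W"), -(8 + 54 / 60 + 0.8 / 3600),
               tolerance = 1e-9)
  expect_equal(parse_coordinate("S 33°30'"), -33.5)
  expect_equal(parse_coordinate("-12.25"), -12.25)
  expect_equal(parse_coordinate(c("41°45'39.6'N", "9°13'37.2'E")),
               c(41 + 45 / 60 + 39.6 / 3600, 9 + 13 / 60 + 37.2 / 3600),
               tolerance = 1e-9)
})

test_that("malformed coordinates fail naming the offending token", {
  expect_error(parse_coordinate("41°xx'04.4''N"), "xx")
  expect_error(parse_coordinate("12°75'N"), "out of \\[0, 60\\)")
  expect_error(parse_coordinate(""), "empty")
})

test_that("projection centre maps to the origin and round-trips within 1 m", {
  proj <- laea_projection(9.2, 42.1)
  ctr <- project_points(tibble::tibble(lon = 9.2, lat = 42.1), proj)
  expect_equal(ctr$x, 0, tolerance = 1e-6)
  expect_equal(ctr$y, 0, tolerance = 1e-6)

  grid <- tidyr::expand_grid(lon = seq(8.5, 9.6, by = 0.25),
                             lat = seq(41.4, 43.0, by = 0.25))
  back <- unproject_points(project_points(grid, proj), proj)
  d_m <- haversine_km(grid$lon, grid$lat, back$lon, back$lat) * 1000
  expect_lt(max(d_m), 1)
})

test_that("projected distances match an independent great-circle oracle", {
  skip_if_not_installed("geosphere")
  proj <- laea_projection(9, 42)
  p <- project_points(tibble::tibble(lon = c(9, 9.05), lat = c(41.95, 42.05)), proj)
  planar <- sqrt(diff(p$x)^2 + diff(p$y)^2)
  oracle <- geosphere::distHaversine(c(9, 41.95), c(9.05, 42.05), r = 6371007.181)
  expect_equal(planar, oracle, tolerance = 0.005)
})

test_that("planar polygon areas are equal-area at island scale", {
  skip_if_not_installed("geosphere")
  proj <- laea_projection(9, 42)
  ring_ll <- tibble::tibble(lon = c(8.6, 9.5, 9.4, 8.7),
                            lat = c(41.5, 41.6, 42.9, 42.8))
  planar <- polygon_area_km2(project_points(ring_ll, proj))
  ellipsoidal <- geosphere::areaPolygon(cbind(ring_ll$lon, ring_ll$lat)) / 1e6
  expect_equal(as.numeric(planar), ellipsoidal, tolerance = 0.005)
})

test_that("antipodal points are rejected by the projection", {
  proj <- laea_projection(0, 0)
  expect_error(project_points(tibble::tibble(lon = 180, lat = 0), proj),
               "antipodal")
})

test_that("convex hull matches the brute-force orientation oracle", {
  expect_equal(nrow(convex_hull(tibble::tibble(x = c(0, 1, 0), y = c(0, 0, 1)))), 3)
  sq <- tibble::tibble(x = c(0, 1, 1, 0, 0.5), y = c(0, 0, 1, 1, 0.5))
  hull <- convex_hull(sq)
  expect_equal(nrow(hull), 4)
  expect_false(any(hull$x == 0.5))

  set.seed(42)
  for (rep in 1:5) {
    pts <- tibble::tibble(x = stats::runif(50) * 1e5, y = stats::runif(50) * 1e5)
    hull <- convex_hull(pts)
    oracle_idx <- brute_hull_vertices(pts$x, pts$y)
    expect_setequal(paste(hull$x, hull$y),
                    paste(pts$x[oracle_idx], pts$y[oracle_idx]))
    # hull idempotence and containment
    expect_equal(dplyr::arrange(convex_hull(hull), x, y),
                 dplyr::arrange(hull, x, y))
    expect_true(all(points_in_rings(pts$x * 0.999 + mean(hull$x) * 0.001,
                                    pts$y * 0.999 + mean(hull$y) * 0.001, hull)))
  }
})

test_that("polygon areas follow the shoelace formula and its invariances", {
  sq <- tibble::tibble(x = c(0, 1000, 1000, 0), y = c(0, 0, 1000, 1000))
  expect_equal(as.numeric(polygon_area_km2(sq)), 1)
  tri <- tibble::tibble(x = c(0, 20000, 0), y = c(0, 0, 30000))
  expect_equal(as.numeric(polygon_area_km2(tri)), 300)

  coll <- tibble::tibble(x = c(0, 1, 2), y = c(0, 1, 2))
  a <- polygon_area_km2(coll)
  expect_equal(as.numeric(a), 0)
  expect_true(attr(a, "degenerate"))
  expect_true(attr(polygon_area_km2(tibble::tibble(x = c(1, 1), y = c(2, 2))),
                   "degenerate"))

  set.seed(7)
  ring <- convex_hull(tibble::tibble(x = stats::rnorm(20) * 1e4,
                                     y = stats::rnorm(20) * 1e4))
  a0 <- as.numeric(polygon_area_km2(ring))
  expect_equal(a0, shoelace_km2(ring$x, ring$y))
  expect_equal(as.numeric(polygon_area_km2(ring[rev(seq_len(nrow(ring))), ])), a0)
  shifted <- dplyr::mutate(ring, x = x + 5e5, y = y - 3e5)
  expect_equal(as.numeric(polygon_area_km2(shifted)), a0)
})

test_that("grid indexing is half-open and partitions the plane", {
  g <- grid_spec(2000)
  pts <- tibble::tibble(x = c(0, 2000, -1, 1999.999, 4000),
                        y = c(0, 0, -1, 0, -4000))
  idx <- cell_index(pts, g)
  expect_equal(idx$cell_i, c(0L, 1L, -1L, 0L, 2L))
  expect_equal(idx$cell_j, c(0L, 0L, -1L, 0L, -2L))

  # partition: every point gets exactly one finite cell, and points on a
  # shared edge go to the higher-index cell only
  set.seed(11)
  r <- tibble::tibble(x = stats::runif(200, -1e4, 1e4),
                      y = stats::runif(200, -1e4, 1e4))
  ri <- cell_index(r, g)
  expect_true(all(is.finite(ri$cell_i) & is.finite(ri$cell_j)))
  expect_true(all(r$x >= g$origin_x + ri$cell_i * g$cell_size &
                  r$x < g$origin_x + (ri$cell_i + 1) * g$cell_size))
})
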