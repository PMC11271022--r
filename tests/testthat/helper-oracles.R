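# Independent oracles used across the suite. Each is a deliberately naive
# re-derivation (brute force, enumeration, explicit rule tables) kept free of
# the code paths it checks.

# O(n^3) convex hull: a point pair is a hull edge iff every other point lies
# on one side of (or on) the line through it. Returns the hull vertex set.
brute_hull_vertices <- function(x, y) {
  n <- length(x)
  on_hull <- rep(FALSE, n)
  for (a in 1:(n - 1)) {
    for (b in (a + 1):n) {
      cr <- (x[b] - x[a]) * (y - y[a]) - (y[b] - y[a]) * (x - x[a])
      if (all(cr <= 1e-9) || all(cr >= -1e-9)) {
        on_hull[a] <- TRUE
        on_hull[b] <- TRUE
      }
    }
  }
  which(on_hull)
}

# exhaustive hypergeometric upper tail: enumerate all choose(N, n) draws of
# n cells from N (K of them habitat) and count draws with >= k habitat cells
enum_hyper_upper <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)   # cells 1..K are the habitat cells
  mean(hits >= k)
}

# explicit criterion B rule table, written as literal nested conditions
redlist_oracle <- function(eoo, aoo, nloc, decline, fragmented) {
  meets <- function(eoo_t, aoo_t, loc_t) {
    range_ok <- (!is.na(eoo) && eoo < eoo_t) || (!is.na(aoo) && aoo < aoo_t)
    a_ok <- isTRUE(fragmented) || nloc <= loc_t
    b_ok <- isTRUE(decline)
    range_ok && a_ok && b_ok
  }
  if (meets(100, 10, 1)) "CR"
  else if (meets(5000, 500, 5)) "EN"
  else if (meets(20000, 2000, 10)) "VU"
  else "LC"
}

# planar shoelace kept separate from the package implementation
shoelace_km2 <- function(x, y) {
  n <- length(x)
  s <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    s <- s + x[i] * y[j] - x[j] * y[i]
  }
  abs(s) / 2 / 1e6
}

# tiny hand-built landscape: every cell land, classes and elevations given as
# matrices (row 1 = southernmost row), 100 m cells anchored at the origin
make_flat_landscape <- function(classes, elevations, cell_size = 100,
                                projection = laea_projection(9, 42)) {
  h <- raster_header(origin_x = 0, origin_y = 0, cell_size = cell_size,
                     n_rows = nrow(classes), n_cols = ncol(classes))
  list(landcover = scape_raster(classes, h, "categorical"),
       elevation = scape_raster(elevations, h, "continuous"),
       header = h, projection = projection)
}

# records placed at given cell centres of a landscape, as lon/lat tibbles
records_at_cells <- function(ls, rows, cols, ...) {
  h <- ls$header
  pts <- tibble::tibble(x = h$origin_x + (cols - 0.5) * h$cell_size,
                        y = h$origin_y + (rows - 0.5) * h$cell_size)
  out <- unproject_points(pts, ls$projection)
  out$id <- sprintf("r%02d", seq_len(nrow(out)))
  extra <- list(...)
  for (nm in names(extra)) out[[nm]] <- extra[[nm]]
  out
}
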