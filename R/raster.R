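# Minimal matrix-backed raster container shared by the land-cover, elevation
# and habitat-mask layers. Rows are indexed south-to-north so that cell (i, j)
# covers the half-open square
#   x in [origin_x + (j-1)*s, origin_x + j*s), y in [origin_y + (i-1)*s, ...)
# matching the grid convention used everywhere else in the package.

#' Raster georeferencing header
#'
#' @param origin_x,origin_y Coordinates of the lower-left corner, metres.
#' @param cell_size Cell edge in metres (default 100, the land-cover
#'   resolution the pipeline assumes).
#' @param n_rows,n_cols Grid dimensions.
#' @param nodata Integer code marking sea / missing cells.
#' @return A `raster_header` object.
#' @export
raster_header <- function(origin_x, origin_y, cell_size = 100, n_rows, n_cols,
                          nodata = -9999L) {
  stopifnot(n_rows > 0, n_cols > 0, cell_size > 0)
  structure(list(origin_x = origin_x, origin_y = origin_y,
                 cell_size = cell_size, n_rows = as.integer(n_rows),
                 n_cols = as.integer(n_cols), nodata = nodata),
            class = "raster_header")
}

same_header <- function(a, b) {
  isTRUE(all.equal(unclass(a)[c("origin_x", "origin_y", "cell_size")],
                   unclass(b)[c("origin_x", "origin_y", "cell_size")])) &&
    a$n_rows == b$n_rows && a$n_cols == b$n_cols
}

#' Construct a raster layer
#'
#' @param values Numeric or integer matrix, `n_rows` x `n_cols`, row 1 the
#'   southernmost row. `NA` entries are treated as nodata.
#' @param header A [raster_header()]; dimensions must match `values`.
#' @param type `"categorical"` (integer class codes) or `"continuous"`.
#' @return A `scape_raster` object.
#' @export
scape_raster <- function(values, header, type = c("continuous", "categorical")) {
  type <- match.arg(type)
  stopifnot(inherits(header, "raster_header"),
            nrow(values) == header$n_rows, ncol(values) == header$n_cols)
  structure(list(values = values, header = header, type = type),
            class = "scape_raster")
}

#' @export
print.scape_raster <- function(x, ...) {
  h <- x$header
  cat(sprintf("%s raster: %d x %d cells of %g m (%.1f km2), origin (%g, %g)\n",
              x$type, h$n_rows, h$n_cols, h$cell_size,
              h$n_rows * h$n_cols * h$cell_size^2 / 1e6, h$origin_x, h$origin_y))
  cat(sprintf("  data cells: %d\n", sum(!is.na(x$values))))
  invisible(x)
}

# cell-centre coordinate vectors (x along columns, y along rows)
raster_x_centers <- function(header) {
  header$origin_x + (seq_len(header$n_cols) - 0.5) * header$cell_size
}
raster_y_centers <- function(header) {
  header$origin_y + (seq_len(header$n_rows) - 0.5) * header$cell_size
}

#' Raster values as a tidy tibble
#'
#' @param x A `scape_raster`.
#' @param ... Unused.
#' @param drop_na Drop nodata cells (default `TRUE`).
#' @return Tibble with cell-centre `x`, `y` (metres) and `value`.
#' @exportS3Method tibble::as_tibble
as_tibble.scape_raster <- function(x, ..., drop_na = TRUE) {
  h <- x$header
  out <- tibble::tibble(
    x = rep(raster_x_centers(h), each = h$n_rows),
    y = rep(raster_y_centers(h), times = h$n_cols),
    value = as.vector(x$values)
  )
  if (drop_na) out <- out[!is.na(out$value), ]
  out
}

#' Sample raster values at point locations
#'
#' @param raster A `scape_raster`.
#' @param x,y Point coordinates in metres.
#' @return Values at the containing cells; `NA` for points off the raster or
#'   on nodata cells.
#' @export
raster_lookup <- function(raster, x, y) {
  h <- raster$header
  j <- floor((x - h$origin_x) / h$cell_size) + 1
  i <- floor((y - h$origin_y) / h$cell_size) + 1
  ok <- i >= 1 & i <= h$n_rows & j >= 1 & j <= h$n_cols & is.finite(i) & is.finite(j)
  out <- rep(NA_real_, length(x))
  out[ok] <- raster$values[cbind(i[ok], j[ok])]
  out
}

# row/column indices of points; NA outside the raster
raster_cell_of <- function(header, x, y) {
  j <- floor((x - header$origin_x) / header$cell_size) + 1
  i <- floor((y - header$origin_y) / header$cell_size) + 1
  bad <- !(i >= 1 & i <= header$n_rows & j >= 1 & j <= header$n_cols)
  i[bad] <- NA_integer_; j[bad] <- NA_integer_
  tibble::tibble(row = as.integer(i), col = as.integer(j))
}

#' Write a raster as an ESRI ASCII grid
#'
#' Plain-text interchange format readable by any GIS. Values are written
#' north-to-south as the format requires.
#'
#' @param raster A `scape_raster`.
#' @param path Output `.asc` file.
#' @export
write_asc <- function(raster, path) {
  h <- raster$header
  v <- raster$values
  v[is.na(v)] <- h$nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", h$n_cols),
    sprintf("nrows %d", h$n_rows),
    sprintf("xllcorner %.6f", h$origin_x),
    sprintf("yllcorner %.6f", h$origin_y),
    sprintf("cellsize %.6f", h$cell_size),
    sprintf("NODATA_value %s", format(h$nodata))
  ), con)
  utils::write.table(v[rev(seq_len(h$n_rows)), , drop = FALSE], con,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path `.asc` file written by [write_asc()] or any GIS.
#' @param type Raster type, `"continuous"` or `"categorical"`.
#' @return A `scape_raster`.
#' @export
read_asc <- function(path, type = "continuous") {
  hdr_lines <- readLines(path, n = 6)
  kv <- strsplit(trimws(hdr_lines), "\\s+")
  key <- tolower(vapply(kv, `[`, "", 1))
  val <- as.numeric(vapply(kv, `[`, "", 2))
  names(val) <- key
  h <- raster_header(origin_x = val[["xllcorner"]], origin_y = val[["yllcorner"]],
                     cell_size = val[["cellsize"]],
                     n_rows = val[["nrows"]], n_cols = val[["ncols"]],
                     nodata = val[["nodata_value"]])
  v <- as.matrix(utils::read.table(path, skip = 6))
  dimnames(v) <- NULL
  v <- v[rev(seq_len(h$n_rows)), , drop = FALSE]
  v[v == h$nodata] <- NA
  scape_raster(v, h, type = type)
}

# contour rings of a value matrix at `level`, in map (x, y) metres.
# grDevices::contourLines treats its first axis as rows, so axes are swapped
# back here. Open (grid-edge-clipped) lines are closed by joining endpoints.
raster_contour <- function(values, header, level) {
  cl <- grDevices::contourLines(x = raster_y_centers(header),
                                y = raster_x_centers(header),
                                z = values, levels = level)
  purrr::map(cl, function(l) tibble::tibble(x = l$y, y = l$x))
}

#' Write polygon rings as GeoJSON
#'
#' Rings given in projected metres are unprojected back to WGS84 longitude /
#' latitude before writing, matching the GeoJSON specification.
#'
#' @param rings Data frame with `x`/`y` columns, or list of them.
#' @param path Output file.
#' @param projection The [laea_projection()] the coordinates live in.
#' @param properties Named list of feature properties.
#' @export
write_geojson_polygon <- function(rings, path, projection, properties = list()) {
  if (is.data.frame(rings)) rings <- list(rings)
  coords <- purrr::map(rings, function(r) {
    ll <- unproject_points(r, projection)
    ring <- cbind(ll$lon, ll$lat)
    if (!all(ring[1, ] == ring[nrow(ring), ])) ring <- rbind(ring, ring[1, ])
    ring
  })
  gj <- list(
    type = "FeatureCollection",
    features = list(list(
      type = "Feature",
      properties = properties,
      geometry = list(type = "MultiPolygon",
                      coordinates = purrr::map(coords, list))
    ))
  )
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = 8)
  invisible(path)
}
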