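# Area of Habitat: infer the habitat model (suitable land-cover classes and
# an elevation band) from occurrence records, intersect it with the rasters
# inside a boundary, and validate the resulting map against the records with
# an upper-tail hypergeometric test (sampling cells without replacement).

#' Infer a habitat model from occurrence records
#'
#' The suitable class set is the set of land-cover codes at the record cells;
#' the elevation band is the min-max of record elevations. Printed record
#' elevations (columns `elev_min_m`/`elev_max_m`, or `elevation_m`) take
#' precedence; records without one are sampled from the elevation raster.
#'
#' @param records Data frame with `lon`, `lat` (and optionally elevation)
#'   columns.
#' @param landcover,elevation [scape_raster()] layers sharing a header.
#' @param projection Optional [laea_projection()]; defaults to one centred on
#'   the record centroid.
#' @param elev_buffer_m Optional symmetric widening of the elevation band
#'   (default 0: exactly the observed min-max).
#' @return A `habitat_model`: `suitable_classes`, `elev_min`, `elev_max`.
#' @export
infer_habitat_model <- function(records, landcover, elevation, projection = NULL,
                                elev_buffer_m = 0) {
  stopifnot(nrow(records) >= 1, same_header(landcover$header, elevation$header))
  if (is.null(projection)) projection <- default_projection(records)
  pts <- project_points(records, projection)
  cls <- raster_lookup(landcover, pts$x, pts$y)
  if (all(is.na(cls))) {
    ids <- if ("id" %in% names(records)) records$id else seq_len(nrow(records))
    stop("no record falls on a land cell of the raster: ",
         paste(ids, collapse = ", "), call. = FALSE)
  }
  lo <- if ("elev_min_m" %in% names(records)) records$elev_min_m
        else if ("elevation_m" %in% names(records)) records$elevation_m
        else rep(NA_real_, nrow(records))
  hi <- if ("elev_max_m" %in% names(records)) records$elev_max_m
        else lo
  sampled <- raster_lookup(elevation, pts$x, pts$y)
  lo <- ifelse(is.na(lo), sampled, lo)
  hi <- ifelse(is.na(hi), sampled, hi)
  if (all(is.na(lo))) stop("no elevation information available for any record", call. = FALSE)
  structure(list(
    suitable_classes = sort(unique(as.integer(stats::na.omit(cls)))),
    elev_min = min(lo, na.rm = TRUE) - elev_buffer_m,
    elev_max = max(hi, na.rm = TRUE) + elev_buffer_m
  ), class = "habitat_model")
}

#' Define a habitat model directly
#'
#' @param suitable_classes Integer land-cover codes considered habitat.
#' @param elev_min,elev_max Elevation band in metres.
#' @return A `habitat_model`.
#' @export
habitat_model <- function(suitable_classes, elev_min = -Inf, elev_max = Inf) {
  stopifnot(length(suitable_classes) >= 1, elev_min <= elev_max)
  structure(list(suitable_classes = sort(unique(as.integer(suitable_classes))),
                 elev_min = elev_min, elev_max = elev_max),
            class = "habitat_model")
}

#' @export
print.habitat_model <- function(x, ...) {
  cat(sprintf("habitat model: classes {%s}, elevation %.0f-%.0f m\n",
              paste(x$suitable_classes, collapse = ", "), x$elev_min, x$elev_max))
  invisible(x)
}

#' Build an Area-of-Habitat map
#'
#' Habitat cells are land cells whose land-cover class is suitable, whose
#' elevation falls inside the model's band, and (when a boundary is given)
#' whose centre lies inside the boundary polygon — typically the EOO hull for
#' a range-clipped map, or no boundary for an island-wide map.
#'
#' @param landcover,elevation [scape_raster()] layers sharing a header.
#' @param model A `habitat_model`.
#' @param boundary Optional polygon (data frame with `x`/`y` in metres, or
#'   list of rings) clipping the analysis domain.
#' @param domain_label Label stored with the map (`"island-wide"` or e.g.
#'   `"EOO-clipped"`).
#' @return An `aoh_map`: `mask` and `domain` logical matrices, `header`,
#'   `area_km2`, `domain_label`.
#' @export
build_aoh <- function(landcover, elevation, model, boundary = NULL,
                      domain_label = if (is.null(boundary)) "island-wide" else "clipped") {
  if (!same_header(landcover$header, elevation$header)) {
    stop("land-cover and elevation rasters do not share a header", call. = FALSE)
  }
  stopifnot(inherits(model, "habitat_model"))
  h <- landcover$header
  cls <- landcover$values
  elev <- elevation$values
  domain <- !is.na(cls)
  if (!is.null(boundary)) {
    cx <- rep(raster_x_centers(h), each = h$n_rows)
    cy <- rep(raster_y_centers(h), times = h$n_cols)
    inside <- matrix(points_in_rings(cx, cy, boundary), h$n_rows, h$n_cols)
    domain <- domain & inside
  }
  mask <- domain & cls %in% model$suitable_classes &
    !is.na(elev) & elev >= model$elev_min & elev <= model$elev_max
  structure(list(mask = mask, domain = domain, header = h,
                 area_km2 = sum(mask) * h$cell_size^2 / 1e6,
                 domain_label = domain_label, model = model),
            class = "aoh_map")
}

#' @export
print.aoh_map <- function(x, ...) {
  cat(sprintf("AOH map (%s): %.1f km2 habitat (%d of %d domain cells)\n",
              x$domain_label, x$area_km2, sum(x$mask), sum(x$domain)))
  invisible(x)
}

#' Validate an AOH map against occurrence records
#'
#' Tests whether occurrences fall in mapped habitat more often than expected
#' when drawing the same number of cells uniformly without replacement from
#' the domain: an upper-tail hypergeometric test with `N` domain cells, `K`
#' habitat cells, `n` distinct record-occupied cells and `k` of those in
#' habitat. Duplicate records in one cell count once, avoiding
#' pseudo-replication.
#'
#' @param aoh An [build_aoh()] map.
#' @param records Data frame with `lon`, `lat` columns.
#' @param projection Optional [laea_projection()].
#' @param alpha Significance level for the `better_than_random` flag
#'   (default 0.05; only the flag is produced, not a significance claim).
#' @return An `aoh_validation`: `N`, `K`, `n`, `k`, `p_value`,
#'   `better_than_random`, `n_excluded` (records off-raster or outside the
#'   domain, reported with a warning).
#' @export
validate_aoh <- function(aoh, records, projection = NULL, alpha = 0.05) {
  stopifnot(inherits(aoh, "aoh_map"), nrow(records) >= 1)
  if (is.null(projection)) projection <- default_projection(records)
  pts <- project_points(records, projection)
  rc <- raster_cell_of(aoh$header, pts$x, pts$y)
  in_domain <- !is.na(rc$row) & aoh$domain[cbind(rc$row, rc$col)]
  n_excluded <- sum(!in_domain)
  if (n_excluded > 0) {
    warning(sprintf("%d record(s) off the raster or outside the domain were excluded",
                    n_excluded), call. = FALSE)
  }
  rc <- rc[in_domain, ]
  cells <- unique(rc)
  N <- sum(aoh$domain)
  K <- sum(aoh$mask)
  n <- nrow(cells)
  if (n < 1) stop("no record falls inside the AOH domain", call. = FALSE)
  if (K < 1) stop("the AOH map contains no habitat cells", call. = FALSE)
  k <- sum(aoh$mask[cbind(cells$row, cells$col)])
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  structure(list(N = N, K = K, n = n, k = k, p_value = p,
                 better_than_random = p <= alpha, alpha = alpha,
                 n_excluded = n_excluded),
            class = "aoh_validation")
}

#' @export
print.aoh_validation <- function(x, ...) {
  cat(sprintf("AOH validation: %d of %d occupied cells in habitat (domain %d cells, %d habitat)\n",
              x$k, x$n, x$N, x$K))
  cat(sprintf("  upper-tail hypergeometric p = %.4g; better than random at alpha=%.2f: %s\n",
              x$p_value, x$alpha, x$better_than_random))
  invisible(x)
}
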