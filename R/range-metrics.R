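# Criterion B range metrics: extent of occurrence (minimum convex polygon),
# area of occupancy (2 x 2 km grid-cell counting), distance-clustered
# locality counts, and the threshold-table classifier.

# IUCN criterion B threshold table (km2 and locality counts); the range
# condition is a strict "less than", locality counts are "at most".
CRITERION_B_THRESHOLDS <- tibble::tibble(
  category      = c("CR", "EN", "VU"),
  eoo_max_km2   = c(100, 5000, 20000),
  aoo_max_km2   = c(10, 500, 2000),
  max_localities = c(1, 5, 10)
)

# default projection for a record set: LAEA centred on the coordinate centroid
default_projection <- function(records) {
  laea_projection(mean(records$lon), mean(records$lat))
}

#' Extent of occurrence (minimum convex polygon)
#'
#' Projects the records into an equal-area plane, takes the convex hull, and
#' returns its area in km2. Per IUCN guidance the EOO may not be smaller than
#' the AOO; pass `aoo_floor_km2` to apply that adjustment.
#'
#' @param records Data frame with `lon`, `lat` columns (decimal degrees).
#' @param projection Optional [laea_projection()]; defaults to one centred on
#'   the record centroid.
#' @param aoo_floor_km2 Optional AOO to floor the EOO at.
#' @return An `eoo_result`: `eoo_km2`, `hull` (tibble of vertices with both
#'   projected and geographic coordinates), `degenerate`, `projection`.
#' @export
compute_eoo <- function(records, projection = NULL, aoo_floor_km2 = NULL) {
  if (nrow(records) < 1) stop("at least one occurrence record is required", call. = FALSE)
  if (is.null(projection)) projection <- default_projection(records)
  pts <- project_points(records, projection)
  hull <- convex_hull(pts)
  area <- polygon_area_km2(hull)
  # areas below 1e-9 km2 (1 mm2) only arise from floating-point noise on
  # collinear or coincident points and are treated as degenerate
  degenerate <- isTRUE(attr(area, "degenerate")) || nrow(hull) < 3 || area < 1e-9
  eoo <- if (area < 1e-9) 0 else as.numeric(area)
  adjusted <- FALSE
  if (!is.null(aoo_floor_km2) && eoo < aoo_floor_km2) {
    eoo <- aoo_floor_km2
    adjusted <- TRUE
  }
  hull <- unproject_points(hull, projection)
  structure(list(eoo_km2 = eoo, hull = hull, degenerate = degenerate,
                 aoo_adjusted = adjusted, projection = projection),
            class = "eoo_result")
}

#' @export
print.eoo_result <- function(x, ...) {
  cat(sprintf("EOO: %.1f km2 (%d hull vertices%s)\n", x$eoo_km2, nrow(x$hull),
              if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

#' Area of occupancy on a 2 x 2 km grid
#'
#' Counts distinct occupied cells of the standard IUCN 2 km grid; AOO is
#' 4 km2 per occupied cell. The grid origin is configurable because AOO
#' depends on grid placement.
#'
#' @param records Data frame with `lon`, `lat` columns.
#' @param projection Optional [laea_projection()].
#' @param grid A [grid_spec()]; default 2,000 m cells anchored at the
#'   projection origin.
#' @return An `aoo_result`: `aoo_km2`, `occupied_cells` (tibble of distinct
#'   `cell_i`, `cell_j`), `n_cells`, `grid`, `projection`.
#' @export
compute_aoo <- function(records, projection = NULL, grid = grid_spec(2000)) {
  if (nrow(records) < 1) stop("at least one occurrence record is required", call. = FALSE)
  if (is.null(projection)) projection <- default_projection(records)
  pts <- project_points(records, projection)
  cells <- dplyr::distinct(cell_index(pts, grid), .data$cell_i, .data$cell_j)
  structure(list(aoo_km2 = 4 * nrow(cells), occupied_cells = cells,
                 n_cells = nrow(cells), grid = grid, projection = projection),
            class = "aoo_result")
}

#' @export
print.aoo_result <- function(x, ...) {
  cat(sprintf("AOO: %d km2 (%d occupied %g-km cells)\n", x$aoo_km2, x$n_cells,
              x$grid$cell_size / 1000))
  invisible(x)
}

#' Count distinct localities by single-linkage distance clustering
#'
#' Two records belong to the same locality when a chain of records, each pair
#' closer than `linkage_km` (great-circle), connects them: the locality count
#' is the number of connected components of that graph.
#'
#' @param records Data frame with `lon`, `lat` columns.
#' @param linkage_km Linkage distance in km (default 10).
#' @return Integer count, with attribute `membership` giving each record's
#'   locality index.
#' @export
count_localities <- function(records, linkage_km = 10) {
  n <- nrow(records)
  stopifnot(n >= 1, linkage_km > 0)
  parent <- seq_len(n)
  find <- function(a) { while (parent[a] != a) a <- parent[a]; a }
  if (n > 1) {
    pairs <- utils::combn(n, 2)
    d <- haversine_km(records$lon[pairs[1, ]], records$lat[pairs[1, ]],
                      records$lon[pairs[2, ]], records$lat[pairs[2, ]])
    for (k in which(d < linkage_km)) {
      ra <- find(pairs[1, k]); rb <- find(pairs[2, k])
      if (ra != rb) parent[ra] <- rb
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  structure(length(unique(roots)), membership = match(roots, unique(roots)))
}

#' Classify a species under IUCN criterion B
#'
#' Applies the criterion B threshold table: B1 on EOO (CR < 100, EN < 5,000,
#' VU < 20,000 km2), B2 on AOO (CR < 10, EN < 500, VU < 2,000 km2), with
#' subcriterion (a) met by severe fragmentation or a locality count at or
#' below the category threshold (CR 1, EN 5, VU 10) and subcriterion (b) by
#' observed continuing decline. A category is assigned when its range
#' condition holds together with at least two subcriteria; with (c) (extreme
#' fluctuations) not evaluated here, that means both (a) and (b).
#'
#' @param eoo_km2,aoo_km2 Range metrics in km2 (`NA` allowed).
#' @param n_localities Number of distinct localities.
#' @param decline_observed Continuing decline in habitat extent/quality
#'   observed? `NA` is treated as unmet and noted.
#' @param severely_fragmented Population severely fragmented? `NA` treated as
#'   unmet and noted.
#' @return A `redlist_assessment`: `category` (LC/VU/EN/CR), `criteria_string`
#'   (e.g. `"B1ab+B2ab"`, empty when not listed), `triggered` (tibble of
#'   per-category threshold outcomes), `notes`.
#' @export
classify_criterion_b <- function(eoo_km2, aoo_km2, n_localities,
                                 decline_observed = FALSE,
                                 severely_fragmented = FALSE) {
  notes <- character(0)
  if (is.na(decline_observed)) {
    notes <- c(notes, "decline flag missing: subcriterion b treated as unmet")
    decline_observed <- FALSE
  }
  if (is.na(severely_fragmented)) {
    notes <- c(notes, "fragmentation flag missing: treated as not fragmented")
    severely_fragmented <- FALSE
  }
  tt <- CRITERION_B_THRESHOLDS
  triggered <- dplyr::mutate(
    tt,
    b1_range = !is.na(eoo_km2) & eoo_km2 < .data$eoo_max_km2,
    b2_range = !is.na(aoo_km2) & aoo_km2 < .data$aoo_max_km2,
    sub_a = severely_fragmented | n_localities <= .data$max_localities,
    sub_b = decline_observed,
    listed = (.data$b1_range | .data$b2_range) & .data$sub_a & .data$sub_b
  )
  category <- "LC"
  criteria <- ""
  hit <- which(triggered$listed)
  if (length(hit) > 0) {
    row <- triggered[hit[1], ]   # table ordered CR > EN > VU: first hit is highest
    category <- row$category
    subletters <- paste0(if (row$sub_a) "a" else "", if (row$sub_b) "b" else "")
    parts <- c(if (row$b1_range) paste0("B1", subletters),
               if (row$b2_range) paste0("B2", subletters))
    criteria <- paste(parts, collapse = "+")
  }
  structure(list(category = category, criteria_string = criteria,
                 triggered = triggered, notes = notes,
                 inputs = tibble::tibble(eoo_km2 = eoo_km2, aoo_km2 = aoo_km2,
                                         n_localities = n_localities,
                                         decline_observed = decline_observed,
                                         severely_fragmented = severely_fragmented)),
            class = "redlist_assessment")
}

#' @export
print.redlist_assessment <- function(x, ...) {
  cat(sprintf("IUCN criterion B assessment: %s%s\n", x$category,
              if (nzchar(x$criteria_string)) paste0(" ", x$criteria_string) else ""))
  cat(sprintf("  EOO %.0f km2, AOO %.0f km2, %d localities; decline=%s, fragmented=%s\n",
              x$inputs$eoo_km2, x$inputs$aoo_km2, x$inputs$n_localities,
              x$inputs$decline_observed, x$inputs$severely_fragmented))
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}

#' Summarise EOO, AOO and localities for a record set
#'
#' Convenience wrapper running [compute_eoo()], [compute_aoo()] and
#' [count_localities()] under one shared projection, with the IUCN
#' EOO >= AOO adjustment applied.
#'
#' @inheritParams compute_eoo
#' @inheritParams count_localities
#' @param aoo_grid Grid for [compute_aoo()].
#' @return A `range_summary` with elements `eoo`, `aoo`, `n_localities`, and
#'   a `summary` tibble row.
#' @export
summarize_range <- function(records, projection = NULL, linkage_km = 10,
                            aoo_grid = grid_spec(2000)) {
  if (is.null(projection)) projection <- default_projection(records)
  aoo <- compute_aoo(records, projection, aoo_grid)
  eoo <- compute_eoo(records, projection, aoo_floor_km2 = aoo$aoo_km2)
  loc <- count_localities(records, linkage_km)
  structure(list(
    eoo = eoo, aoo = aoo, n_localities = as.integer(loc),
    locality_membership = attr(loc, "membership"),
    projection = projection,
    summary = tibble::tibble(eoo_km2 = eoo$eoo_km2, aoo_km2 = aoo$aoo_km2,
                             n_localities = as.integer(loc),
                             n_records = nrow(records),
                             linkage_km = linkage_km)
  ), class = "range_summary")
}

#' @export
print.range_summary <- function(x, ...) {
  print(x$summary)
  invisible(x)
}
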