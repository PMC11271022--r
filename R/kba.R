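# Key Biodiversity Area scoping: scan a 10 x 10 km grid over the AOH, score
# each grid cell by the fraction of the species' global population it holds
# (habitat area as the population proxy), and flag cells crossing the KBA
# criterion A1 (threatened species) and B1 (geographically restricted
# species) thresholds. Potential KBA boundaries are the habitat cells, at
# raster resolution, inside triggering grid cells.

#' KBA criterion thresholds
#'
#' Defaults follow the KBA Standard for a CR/EN species: criterion A1
#' triggers at >= 0.5% of the global population at the site, criterion B1 at
#' >= 10%. Both are mandatory configuration so other species or categories
#' can be assessed.
#'
#' @param a1_fraction,b1_fraction Trigger fractions, `0 < a1 < b1 <= 1`.
#' @return A `kba_thresholds` object.
#' @export
kba_thresholds <- function(a1_fraction = 0.005, b1_fraction = 0.10) {
  stopifnot(a1_fraction > 0, a1_fraction < b1_fraction, b1_fraction <= 1)
  structure(list(a1_fraction = a1_fraction, b1_fraction = b1_fraction),
            class = "kba_thresholds")
}

#' Scope potential KBAs on a scanning grid
#'
#' @param aoh An [build_aoh()] map; its habitat area is the global-population
#'   denominator.
#' @param grid A [grid_spec()], default 10,000 m cells anchored at the
#'   projection origin (a grid-shift sweep can be run by varying the origin).
#' @param thresholds A [kba_thresholds()].
#' @return A `kba_result`: `cell_fractions` (tibble with per-grid-cell
#'   habitat area, population fraction and trigger flags), `kba_mask`
#'   (habitat cells inside triggering cells, raster resolution),
#'   `total_area_km2`, `pct_of_aoh`, `grid`, `thresholds`.
#' @export
scope_kba <- function(aoh, grid = grid_spec(10000), thresholds = kba_thresholds()) {
  stopifnot(inherits(aoh, "aoh_map"), inherits(grid, "grid_spec"))
  if (sum(aoh$mask) == 0) stop("AOH map has zero habitat area", call. = FALSE)
  h <- aoh$header
  hab_idx <- which(aoh$mask)
  ij <- arrayInd(hab_idx, dim(aoh$mask))
  cx <- h$origin_x + (ij[, 2] - 0.5) * h$cell_size
  cy <- h$origin_y + (ij[, 1] - 0.5) * h$cell_size
  gi <- floor((cx - grid$origin_x) / grid$cell_size)
  gj <- floor((cy - grid$origin_y) / grid$cell_size)

  cell_area_km2 <- h$cell_size^2 / 1e6
  cells <- tibble::tibble(cell_i = gi, cell_j = gj) |>
    dplyr::count(.data$cell_i, .data$cell_j, name = "n_habitat_cells") |>
    dplyr::mutate(
      habitat_km2 = .data$n_habitat_cells * cell_area_km2,
      fraction = .data$n_habitat_cells / length(hab_idx),
      triggers_a1 = .data$fraction >= thresholds$a1_fraction,
      triggers_b1 = .data$fraction >= thresholds$b1_fraction
    )

  triggering <- cells$triggers_a1 | cells$triggers_b1
  key <- paste(gi, gj)
  in_trigger <- key %in% paste(cells$cell_i[triggering], cells$cell_j[triggering])
  kba_mask <- matrix(FALSE, h$n_rows, h$n_cols)
  kba_mask[hab_idx[in_trigger]] <- TRUE

  structure(list(
    cell_fractions = cells,
    triggered_cells = list(
      A1 = cells[cells$triggers_a1, c("cell_i", "cell_j")],
      B1 = cells[cells$triggers_b1, c("cell_i", "cell_j")]
    ),
    kba_mask = kba_mask,
    header = h,
    total_area_km2 = sum(kba_mask) * cell_area_km2,
    pct_of_aoh = 100 * sum(kba_mask) / sum(aoh$mask),
    grid = grid,
    thresholds = thresholds
  ), class = "kba_result")
}

#' @export
print.kba_result <- function(x, ...) {
  cat(sprintf("KBA scoping: %d grid cell(s) trigger A1, %d trigger B1\n",
              nrow(x$triggered_cells$A1), nrow(x$triggered_cells$B1)))
  cat(sprintf("  potential KBA area %.1f km2 (%.1f%% of AOH)\n",
              x$total_area_km2, x$pct_of_aoh))
  invisible(x)
}

#' Summarise a KBA scoping result against its AOH
#'
#' @param result A [scope_kba()] result.
#' @param aoh The [build_aoh()] map it was scoped on.
#' @return One-row tibble: `total_area_km2`, `pct_of_aoh`, trigger counts.
#' @export
summarize_kba <- function(result, aoh) {
  stopifnot(inherits(result, "kba_result"), inherits(aoh, "aoh_map"))
  if (!same_header(result$header, aoh$header)) {
    stop("KBA result and AOH map do not share a header", call. = FALSE)
  }
  tibble::tibble(
    total_area_km2 = result$total_area_km2,
    pct_of_aoh = 100 * sum(result$kba_mask & aoh$mask) / sum(aoh$mask),
    n_cells_a1 = nrow(result$triggered_cells$A1),
    n_cells_b1 = nrow(result$triggered_cells$B1)
  )
}

#' Protected-area coverage of the scoped KBAs
#'
#' Percentage of the potential-KBA area (the `kba_mask`) lying inside the
#' protected areas; membership is by raster cell centre.
#'
#' @param result A [scope_kba()] result.
#' @param protected_areas A [generate_protected_area()] object, a polygon
#'   (data frame with `x`/`y` metres), or a list of such rings.
#' @return Percentage in `[0, 100]`.
#' @export
pa_overlap <- function(result, protected_areas) {
  stopifnot(inherits(result, "kba_result"))
  idx <- which(result$kba_mask)
  if (length(idx) == 0) stop("KBA mask is empty", call. = FALSE)
  h <- result$header
  if (inherits(protected_areas, "protected_area") &&
      same_header(h, protected_areas$header)) {
    inside <- protected_areas$mask[idx]
  } else {
    rings <- if (inherits(protected_areas, "protected_area")) protected_areas$rings
             else protected_areas
    ij <- arrayInd(idx, dim(result$kba_mask))
    cx <- h$origin_x + (ij[, 2] - 0.5) * h$cell_size
    cy <- h$origin_y + (ij[, 1] - 0.5) * h$cell_size
    inside <- points_in_rings(cx, cy, rings)
  }
  100 * sum(inside) / length(idx)
}
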